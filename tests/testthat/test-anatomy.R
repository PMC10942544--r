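test_that("bouton counts are axonal length over inter-bouton distance", {
  expect_equal(round(bouton_count(3236, 162), 2), 19.98)
  expect_equal(round(bouton_count(3236, 284), 2), 11.39)
  expect_equal(bouton_count(57, 57), 1)
  expect_error(bouton_count(-1, 2), "positive")
  expect_error(bouton_count(10, 0), "positive")
})

test_that("axonal length splits multiply region and layer fractions", {
  out <- split_axonal_length(1e5, 0.275, c(SR = 0.64, SP = 0.15, SO = 0.21))
  expect_close(out, c(SR = 17600, SP = 4125, SO = 5775), tol = 1e-9)

  all_sr <- split_axonal_length(12345, 1.0, c(SR = 1.0))
  expect_equal(unname(all_sr), 12345)

  ca3c <- split_axonal_length(1e5, 0.641, c(SR = 0.94, SP = 0.03, SO = 0.03))
  expect_equal(unname(round(ca3c["SR"])), 60254)

  expect_error(split_axonal_length(100, 1.5, c(SR = 1)), "region_fraction")
  expect_error(split_axonal_length(100, 0.5, c(SR = 0.8, SO = 0.4)),
               "sum to <= 1")
})

test_that("expected contacts follow the Poisson apposition geometry", {
  expect_close(expected_contacts(10, 1000, 1, pi * 1e4), 1.0, tol = 1e-12)
  lam <- expected_contacts(7, 1234, 1.5, 2e8)
  expect_close(expected_contacts(7, 1234, 1.5, 4e8), lam / 2, tol = 1e-12)
  expect_close(expected_contacts(14, 1234, 1.5, 2e8), lam * 2, tol = 1e-12)
  # additivity over parcels
  lam_parts <- expected_contacts(c(3, 4), c(500, 800), 1, 1e7)
  expect_close(sum(lam_parts),
               expected_contacts(3, 500, 1, 1e7) +
                 expected_contacts(4, 800, 1, 1e7), tol = 1e-12)
})

test_that("pair estimates obey the zero-truncated Poisson closed forms", {
  est <- pair_estimate(0.2, f = 1)
  expect_equal(round(est$p, 4), 0.1813)
  expect_equal(round(est$n_contacts, 4), 1.1033)

  # limits
  expect_close(pair_estimate(1e-9)$n_contacts, 1.0, tol = 1e-6)
  big <- pair_estimate(50, f = 0.7)
  expect_close(big$n_contacts, 50, tol = 1e-6)
  expect_close(big$p, 0.7, tol = 1e-6)

  expect_error(pair_estimate(0), "positive")
  expect_error(pair_estimate(1, f = 0), "f")
})

test_that("pair-estimate monotonicity and bounds hold over a lambda sweep", {
  lam <- 10^seq(-4, 1.5, length.out = 40)
  for (f in c(0.2, 1)) {
    est <- pair_estimate(lam, f)
    expect_true(all(est$n_contacts >= 1))
    expect_true(all(diff(est$n_contacts) > 0))
    expect_true(all(diff(est$p) > 0))
    expect_true(all(est$p <= f + 1e-12))
  }
  expect_true(all(pair_estimate(0.5, 0.9)$p > pair_estimate(0.5, 0.3)$p))
})

test_that("the contact model matches a Monte-Carlo apposition oracle", {
  # boutons uniform in a cube; a straight dendritic segment through the
  # middle; an apposition is a bouton within distance r of the segment
  set.seed(99)
  side <- 100
  V <- side^3
  L_d <- 60
  r <- 2
  N_b <- 200
  lambda_model <- expected_contacts(N_b, L_d, r, V)
  seg_a <- c(20, side / 2, side / 2)
  seg_b <- c(80, side / 2, side / 2)
  n_rep <- 2000
  counts <- vapply(seq_len(n_rep), function(i) {
    pts <- matrix(runif(3 * N_b, 0, side), ncol = 3)
    # distance to the x-aligned segment
    dx <- pmin(pmax(pts[, 1], seg_a[1]), seg_b[1])
    d <- sqrt((pts[, 1] - dx)^2 + (pts[, 2] - seg_a[2])^2 +
                (pts[, 3] - seg_a[3])^2)
    sum(d <= r)
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - lambda_model), 3 * se)
})

test_that("calibration inverts the closed forms exactly", {
  truth <- pair_estimate(0.37, f = 0.002)
  cal <- calibrate_pair_estimate(truth$p, truth$n_contacts)
  expect_close(cal$lambda, 0.37, tol = 1e-8)
  expect_close(cal$f, 0.002, tol = 1e-10)

  cal2 <- calibrate_pair_estimate(truth$p, truth$n_contacts,
                                  N_b = 11.39, L_d = 4000, V_hull = 1e9)
  lam_back <- expected_contacts(11.39, 4000, cal2$r, 1e9)
  expect_close(lam_back, 0.37, tol = 1e-8)
})

test_that("mossy-fiber estimates are restricted to SL and flag gaps", {
  targets <- data.frame(
    post_type = c("CA3 Pyramidal", "CA3 Basket", "broken"),
    target_class = c("pyramidal_ca3", "interneuron", "interneuron"),
    L_d_SL = c(4000, 2500, NA),
    stringsAsFactors = FALSE
  )
  out <- mossy_fiber_estimates(targets, V_hull = 5e8, r = 1, f = 0.001)
  expect_false(out$flagged[1L])
  expect_true(out$flagged[3L])
  expect_true(is.na(out$p[3L]))
  # interneuron d_ib (67.4) gives more boutons than pyramidal (284)
  lam_pyr <- expected_contacts(bouton_count(3236, 284), 4000, 1, 5e8)
  expect_close(out$lambda[1L], lam_pyr, tol = 1e-12)
  expect_gt(out$lambda[2L] / out$L_d_SL[2L], out$lambda[1L] / out$L_d_SL[1L])
  expect_error(mossy_fiber_estimates(
    data.frame(post_type = "x", target_class = "granule", L_d_SL = 1),
    V_hull = 1), "target class")
})

test_that("Schaffer estimates aggregate lambda over layers like brute force", {
  targets <- data.frame(
    post_type = c("CA1 Pyramidal", "CA1 SO-only", "twin-a", "twin-b"),
    L_d_SR = c(3000, NA, 1000, 1000),
    L_d_SP = c(200, NA, 100, 100),
    L_d_SO = c(1500, 2000, 500, 500),
    stringsAsFactors = FALSE
  )
  fr <- c(SR = 0.64, SP = 0.15, SO = 0.21)
  dib <- c(SR = 4.1, SP = 4.1, SO = 5.8)
  out <- schaffer_estimates(1e5, 0.275, fr, dib, targets,
                            V_hull = 1e9, r = 1, f = 0.01)
  L_a <- split_axonal_length(1e5, 0.275, fr)
  lam_oracle <- sum(vapply(names(fr), function(q) {
    expected_contacts(bouton_count(L_a[[q]], dib[[q]]),
                      targets[1L, paste0("L_d_", q)], 1, 1e9)
  }, numeric(1)))
  expect_close(out$lambda[1L], lam_oracle, tol = 1e-10)
  # symmetric inputs give identical estimates
  expect_equal(out$lambda[3L], out$lambda[4L])
  expect_equal(out$p[3L], out$p[4L])
  # NA layers contribute nothing but the row still resolves via SO
  expect_false(out$flagged[2L])
  expect_close(out$lambda[2L],
               expected_contacts(bouton_count(L_a[["SO"]], 5.8), 2000, 1, 1e9),
               tol = 1e-10)
})

test_that("CA3 vs CA3c sources differ only via fractions and SR spacing", {
  targets <- data.frame(post_type = "CA1 Pyramidal",
                        L_d_SR = 3000, L_d_SP = 200, L_d_SO = 1500,
                        stringsAsFactors = FALSE)
  ca3 <- schaffer_estimates(1e5, 0.275, c(SR = 0.64, SP = 0.15, SO = 0.21),
                            c(SR = 4.1, SP = 4.1, SO = 5.8),
                            targets, V_hull = 1e9)
  ca3c <- schaffer_estimates(1e5, 0.641, c(SR = 0.94, SP = 0.03, SO = 0.03),
                             c(SR = 5.5, SP = 5.5, SO = 5.8),
                             targets, V_hull = 1e9)
  expect_false(isTRUE(all.equal(ca3$lambda, ca3c$lambda)))
  expect_gt(ca3c$lambda, ca3$lambda)  # more length into CA1 SR for CA3c
})

test_that("inter-bouton averaging reproduces conventional pooling", {
  expect_equal(average_interbouton(c(3.7, 4.4, 4.29)), 4.1)
  expect_equal(average_interbouton(5.5), 5.5)
  expect_equal(average_interbouton(c(2, 4)), 3.0)
  expect_error(average_interbouton(numeric(0)), "empty")
  expect_error(average_interbouton(c(3, -1)), "positive")
})
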