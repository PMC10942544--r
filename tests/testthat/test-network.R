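rs <- izhikevich_preset("regular_spiking")
fs <- izhikevich_preset("fast_spiking")

pop <- function(name, class, n, izh = if (class == "excitatory") rs else fs) {
  population_spec(structure(name, class_label = class), n = n,
                  izhikevich = izh)
}

test_that("missing projection fields resolve to flagged class defaults", {
  ee <- resolve_missing(projection_spec("A", "B"), "excitatory", "excitatory")
  expect_equal(ee$p, 0.0117)
  expect_equal(unname(ee$provenance["p"]), "default")

  ii <- resolve_missing(projection_spec("A", "B"), "inhibitory", "inhibitory")
  expect_equal(ii$p, 0.00423)
  expect_equal(resolve_missing(projection_spec("A", "B"), "excitatory",
                               "inhibitory")$p, 0.0237)
  expect_equal(resolve_missing(projection_spec("A", "B"), "inhibitory",
                               "excitatory")$p, 0.00684)

  # fully specified specs pass through untouched, all flags measured
  full <- projection_spec("A", "B", p = 0.05, n_contacts = 2, g = 1,
                          tau_d = 5, tau_r = 300, tau_f = 40, U = 0.2,
                          E_rev = 0, delay = 1.5)
  res <- resolve_missing(full, "excitatory", "excitatory")
  expect_equal(res$p, 0.05)
  expect_true(all(res$provenance == "measured"))
  # substituted synaptic constants are flagged too
  expect_equal(unname(ee$provenance["g"]), "default")
})

test_that("wiring respects degenerate probabilities exactly", {
  pr <- function(p) resolve_missing(projection_spec("E", "I", p = p),
                                    "excitatory", "inhibitory")
  pops <- list(pop("E", "excitatory", 10), pop("I", "inhibitory", 10))
  all_on <- instantiate_network(pops, list(pr(1)), seed = 1)
  expect_length(all_on$synapses[[1L]]$pre_local, 100L)
  none <- instantiate_network(pops, list(pr(0)), seed = 1)
  expect_length(none$synapses[[1L]]$pre_local, 0L)
})

test_that("autapses are excluded but within-type pairs are wired", {
  pr <- resolve_missing(projection_spec("E", "E", p = 1),
                        "excitatory", "excitatory")
  net <- instantiate_network(list(pop("E", "excitatory", 7)), list(pr),
                             seed = 2)
  s <- net$synapses[[1L]]
  expect_length(s$pre_local, 7L * 6L)
  expect_true(all(s$pre_local != s$post_local))
})

test_that("synapse counts match the binomial expectation over seeds", {
  pops <- list(pop("E", "excitatory", 100), pop("I", "inhibitory", 100))
  pr <- resolve_missing(projection_spec("E", "I", p = 0.1),
                        "excitatory", "inhibitory")
  counts <- vapply(1:50, function(seed) {
    length(instantiate_network(pops, list(pr), seed = seed)$synapses[[1L]]$pre_local)
  }, numeric(1))
  M <- 100 * 100
  sigma_mean <- sqrt(M * 0.1 * 0.9) / sqrt(50)
  expect_lt(abs(mean(counts) - M * 0.1), 3 * sigma_mean)
})

test_that("contact counts are shifted-Poisson with the requested mean", {
  pops <- list(pop("E", "excitatory", 60), pop("I", "inhibitory", 60))
  pr <- resolve_missing(projection_spec("E", "I", p = 1, n_contacts = 2.5),
                        "excitatory", "inhibitory")
  net <- instantiate_network(pops, list(pr), seed = 3)
  contacts <- net$synapses[[1L]]$contacts
  expect_true(all(contacts >= 1L))
  se <- sd(contacts) / sqrt(length(contacts))
  expect_lt(abs(mean(contacts) - 2.5), 4 * se)
})

test_that("identical seeds give bitwise-identical rasters", {
  pops <- list(pop("E", "excitatory", 40), pop("I", "inhibitory", 10))
  prs <- list(
    resolve_missing(projection_spec("E", "I", p = 0.3, g = 2),
                    "excitatory", "inhibitory"),
    resolve_missing(projection_spec("I", "E", p = 0.3, g = 2),
                    "inhibitory", "excitatory"))
  net <- instantiate_network(pops, prs, seed = 9)
  drv <- list(E = list(mean = 120, sd = 40), I = list(mean = 60, sd = 20))
  r1 <- run_network(net, drv, dt = 0.1, T = 300, seed = 17)
  r2 <- run_network(net, drv, dt = 0.1, T = 300, seed = 17)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$lfp, r2$lfp)
  r3 <- run_network(net, drv, dt = 0.1, T = 300, seed = 18)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("wiring and drive use separate random streams", {
  pops <- list(pop("E", "excitatory", 30), pop("I", "inhibitory", 10))
  pr <- resolve_missing(projection_spec("E", "I", p = 0.2),
                        "excitatory", "inhibitory")
  n1 <- instantiate_network(pops, list(pr), seed = 5)
  n2 <- instantiate_network(pops, list(pr), seed = 5)
  expect_identical(n1$synapses[[1L]]$pre_local, n2$synapses[[1L]]$pre_local)
})

test_that("a one-neuron network reproduces the standalone integrator", {
  net <- instantiate_network(list(pop("solo", "excitatory", 1)), list(),
                             seed = 1)
  run <- run_network(net, drive = list(solo = list(mean = 100, sd = 0)),
                     dt = 0.1, T = 500, seed = 2)
  ref <- izhikevich_integrate(rs, 100, dt = 0.1, T = 500)
  expect_equal(run$traces$solo[, 1L], ref$v[-1L])
  expect_equal(run$spikes$t, ref$train$times)
})

test_that("a silent network stays silent and spikes propagate causally", {
  pops <- list(pop("E", "excitatory", 5), pop("I", "inhibitory", 5))
  pr <- resolve_missing(projection_spec("E", "I", p = 1, g = 8, delay = 2),
                        "excitatory", "inhibitory")
  net <- instantiate_network(pops, list(pr), seed = 4)

  quiet <- run_network(net, drive = list(), dt = 0.1, T = 200, seed = 1)
  expect_equal(nrow(quiet$spikes), 0L)
  expect_true(all(quiet$lfp == 0))

  # drive E only: I spikes must lag the first E spike by at least the delay
  run <- run_network(net, drive = list(E = list(mean = 200, sd = 0)),
                     dt = 0.1, T = 400, seed = 1)
  e_first <- min(run$spikes$t[run$spikes$population == "E"])
  i_times <- run$spikes$t[run$spikes$population == "I"]
  expect_gt(length(i_times), 0L)
  expect_gte(min(i_times), e_first + 2)
})

test_that("expected synapse totals follow p * N_pre * N_post on fixtures", {
  pops <- list(pop("A", "excitatory", 80), pop("B", "inhibitory", 50))
  prs <- list(
    resolve_missing(projection_spec("A", "B", p = 0.2), "excitatory",
                    "inhibitory"),
    resolve_missing(projection_spec("A", "A", p = 0.1), "excitatory",
                    "excitatory"))
  totals <- vapply(1:30, function(seed) {
    net <- instantiate_network(pops, prs, seed = seed)
    sum(vapply(net$synapses, function(s) length(s$pre_local), numeric(1)))
  }, numeric(1))
  expected <- 0.2 * 80 * 50 + 0.1 * 80 * 79
  sigma <- sqrt(0.2 * 0.8 * 80 * 50 + 0.1 * 0.9 * 80 * 79) / sqrt(30)
  expect_lt(abs(mean(totals) - expected), 3 * sigma)
})

test_that("the band-pass responds correctly to pure tones", {
  dt <- 0.1
  tt <- seq(dt, 3000, by = dt)
  theta_tone <- sin(2 * pi * 8 * tt / 1000)

  out_theta <- lfp_filter(theta_tone, "theta", dt)
  mid <- seq(round(length(tt) * 0.3), round(length(tt) * 0.7))
  expect_gte(max(abs(out_theta[mid])), 0.9)

  out_ripple <- lfp_filter(theta_tone, "ripple", dt)
  expect_lte(max(abs(out_ripple[mid])), 0.05)

  expect_equal(lfp_filter(numeric(5000), "gamma", dt), numeric(5000))
  expect_length(out_theta, length(theta_tone))
  expect_error(lfp_filter(theta_tone, c(150, 6000), dt), "Nyquist")
  expect_error(lfp_filter(theta_tone, c(12, 4), dt), "band")

  bands <- lfp_bands()
  expect_equal(bands$theta, c(4, 12))
  expect_equal(bands$gamma, c(25, 100))
  expect_equal(bands$ripple, c(150, 200))
})

test_that("network configs round-trip through YAML", {
  cfg <- list(
    populations = list(
      list(name = "E", class = "excitatory", n = 10L,
           izhikevich = "regular_spiking"),
      list(name = "I", class = "inhibitory", n = 5L,
           izhikevich = "fast_spiking")),
    projections = list(list(pre = "E", post = "I", p = 0.5)),
    drive = list(E = list(mean = 100, sd = 0)),
    dt = 0.1, T = 100, seed = 3L)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  parsed <- read_network_config(path)
  expect_length(parsed$populations, 2L)
  expect_equal(parsed$projections[[1L]]$p, 0.5)
  expect_equal(parsed$projections[[1L]]$tau_r, 400)  # engine default
  net <- instantiate_network(parsed$populations, parsed$projections,
                             seed = parsed$seed)
  run <- run_network(net, parsed$drive, dt = parsed$dt, T = parsed$T,
                     seed = parsed$seed)
  expect_s3_class(run, "network_run")
})
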