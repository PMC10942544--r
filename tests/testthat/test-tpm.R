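pars <- tpm_params(g = 1.5, tau_d = 10, tau_r = 500, tau_f = 80, U = 0.3)

test_that("inter-event decay follows the analytic forms", {
  st <- tpm_state()
  st$u <- 0.4; st$R <- 0.5; st$g_t <- 2

  expect_equal(tpm_evolve(st, 0, pars), st)  # identity at dt = 0

  far <- tpm_evolve(st, 1e6, pars)
  expect_close(far$u, 0, tol = 1e-12)
  expect_close(far$R, 1, tol = 1e-12)
  expect_close(far$g_t, 0, tol = 1e-12)

  # semigroup: two half-steps equal one full step
  one <- tpm_evolve(st, 37.5, pars)
  two <- tpm_evolve(tpm_evolve(st, 18.75, pars), 18.75, pars)
  expect_close(unlist(one), unlist(two), tol = 1e-12)

  expect_error(tpm_evolve(st, -1, pars), "nonnegative")
})

test_that("spike updates release the documented fractions", {
  first <- tpm_on_spike(tpm_state(), pars)
  expect_equal(first$amplitude, pars$g * pars$U)
  expect_equal(first$state$u, pars$U)
  expect_equal(first$state$R, 1 - pars$U)

  # U = 1: the first spike exhausts the resources; an immediate second
  # spike releases nothing
  all_in <- tpm_params(g = 1, tau_d = 10, tau_r = 500, tau_f = 80, U = 1)
  s1 <- tpm_on_spike(tpm_state(), all_in)
  s2 <- tpm_on_spike(s1$state, all_in)
  expect_equal(s2$amplitude, 0)
})

test_that("periodic trains reach the closed-form facilitation fixed point", {
  fac <- tpm_params(g = 1, tau_d = 5, tau_r = 50, tau_f = 300, U = 0.15)
  isi <- 40
  st <- tpm_state()
  for (i in 1:200) {
    st <- tpm_evolve(st, isi, fac)
    st <- tpm_on_spike(st, fac)$state
  }
  expect_close(st$u, tpm_steady_u(fac, isi), tol = 1e-10)
})

test_that("PSC trains show depression and facilitation in the right regimes", {
  # depressing: slow recovery, fast facilitation decay
  dep <- tpm_params(g = 1, tau_d = 5, tau_r = 800, tau_f = 10, U = 0.5)
  train <- seq(0, 180, by = 20)
  out_dep <- tpm_psc_train(dep, train, V_hold = -70)
  expect_true(all(diff(out_dep$amplitudes) <= 1e-12))

  # facilitating: slow facilitation, fast recovery, small U
  fac <- tpm_params(g = 1, tau_d = 5, tau_r = 20, tau_f = 900, U = 0.05)
  out_fac <- tpm_psc_train(fac, train, V_hold = -70)
  expect_gt(out_fac$amplitudes[2L], out_fac$amplitudes[1L])

  # single spike: current scales as g U (E_rev - V_hold)
  one <- tpm_psc_train(pars, 0, V_hold = -70)
  expect_close(max(one$I), pars$g * pars$U * (0 - -70), tol = 1e-6)
  expect_error(tpm_psc_train(pars, c(10, 5)), "increasing")
})

test_that("u and R stay in [0, 1] and resources balance releases", {
  set.seed(33)
  for (rep in 1:20) {
    prm <- tpm_params(g = runif(1, 0.1, 5), tau_d = runif(1, 2, 20),
                      tau_r = runif(1, 20, 1000), tau_f = runif(1, 5, 1000),
                      U = runif(1, 0.02, 1))
    st <- tpm_state()
    t_last <- 0
    for (spk in sort(runif(30, 0, 500))) {
      st <- tpm_evolve(st, spk - t_last, prm)
      R_before <- st$R
      hit <- tpm_on_spike(st, prm)
      st <- hit$state
      expect_true(st$u >= 0 && st$u <= 1)
      expect_true(st$R >= 0 && st$R <= 1)
      # conservation: R drops by exactly the released fraction
      expect_close(R_before - st$R, hit$amplitude / prm$g, tol = 1e-12)
      t_last <- spk
    }
  }
})

test_that("event-driven updates equal clock-driven stepping within 0.1%", {
  # clock-driven comparator: per-step exponential decay on a 0.01 ms grid
  # with spikes snapped to grid points
  set.seed(44)
  dt <- 0.01
  for (rep in 1:5) {
    prm <- tpm_params(g = 2, tau_d = runif(1, 3, 15),
                      tau_r = runif(1, 100, 800), tau_f = runif(1, 20, 500),
                      U = runif(1, 0.1, 0.6))
    spikes <- sort(sample(seq(10, 490, by = 10), 12)) + 0.5
    spikes <- round(spikes / dt) * dt
    T_end <- 500

    # event-driven
    st <- tpm_state()
    t_last <- 0
    for (spk in spikes) {
      st <- tpm_evolve(st, spk - t_last, prm)
      st <- tpm_on_spike(st, prm)$state
      t_last <- spk
    }
    st <- tpm_evolve(st, T_end - t_last, prm)

    # clock-driven
    fd <- exp(-dt / prm$tau_f); rd <- exp(-dt / prm$tau_r)
    gd <- exp(-dt / prm$tau_d)
    u <- 0; R <- 1; g_t <- 0
    steps <- round(T_end / dt)
    spike_steps <- round(spikes / dt)
    is_spike <- logical(steps)
    is_spike[spike_steps] <- TRUE
    for (s in seq_len(steps)) {
      u <- u * fd; R <- 1 - (1 - R) * rd; g_t <- g_t * gd
      if (is_spike[s]) {
        u <- u + prm$U * (1 - u)
        rel <- u * R
        R <- R - rel
        g_t <- g_t + prm$g * rel
      }
    }
    expect_lt(abs(st$u - u) / max(u, 1e-9), 1e-3)
    expect_lt(abs(st$R - R) / max(R, 1e-9), 1e-3)
    expect_lt(abs(st$g_t - g_t) / max(g_t, 1e-9), 1e-3)
  }
})

test_that("transfer strength is the conductance transient's integral", {
  expect_equal(transfer_strength(tpm_params(1, 10, 100, 100, 0.5)), 10)
  expect_equal(transfer_strength(tpm_params(2, 10, 100, 100, 0.5)), 20)
  # numeric integral of g e^(-t/tau_d)
  tt <- seq(0, 400, by = 0.001)
  num <- sum(pars$g * exp(-tt / pars$tau_d)) * 0.001
  expect_close(num, transfer_strength(pars), tol = 1e-2)
})
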