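test_that("rest is a fixed point to machine tolerance", {
  p <- izhikevich_preset("regular_spiking")
  out <- izhikevich_integrate(p, I = 0, dt = 0.1, T = 1000)  # 1e4 steps
  expect_equal(max(abs(out$v - p$v_r)), 0)
  expect_equal(max(abs(out$u)), 0)
  expect_length(out$train$times, 0L)
})

test_that("spike counts agree with a dt/10 reference integration", {
  p <- izhikevich_preset("regular_spiking")
  for (I in c(100, 150)) {
    coarse <- length(izhikevich_integrate(p, I, dt = 0.1, T = 1000)$train$times)
    fine <- length(izhikevich_integrate(p, I, dt = 0.01, T = 1000)$train$times)
    expect_equal(coarse, fine)
  }
})

test_that("halving dt changes spike counts by at most one", {
  p <- izhikevich_preset("regular_spiking")
  for (I in c(60, 100, 150, 250)) {
    n1 <- length(izhikevich_integrate(p, I, dt = 0.1, T = 1000)$train$times)
    n2 <- length(izhikevich_integrate(p, I, dt = 0.05, T = 1000)$train$times)
    expect_lte(abs(n1 - n2), 1L)
  }
})

test_that("a current pulse evokes spikes only inside the pulse window", {
  p <- izhikevich_preset("regular_spiking")
  pulse <- function(t) ifelse(t >= 200 & t < 1200, 250, 0)
  out <- izhikevich_integrate(p, pulse, dt = 0.1, T = 1500,
                              stim_window = c(200, 1200))
  expect_gt(length(out$train$times), 0L)
  expect_true(all(out$train$times >= 200 & out$train$times <= 1210))
})

test_that("diverging parameters raise an integration error naming the step", {
  bad <- izhikevich_params(C = 0.5, k = 50, v_r = -60, v_t = -40,
                           v_peak = 1e300, v_min = -50, a = 0.01, b = 0,
                           d = 0)
  expect_error(izhikevich_integrate(bad, 1e5, dt = 1, T = 100), "step")
})

test_that("F-I curves are monotone with a rheobase for tonic regimes", {
  p <- izhikevich_preset("fast_spiking")
  fi <- f_i_curve(p, 0, 500, step = 10, duration = 500)
  expect_true(all(diff(fi$curve$rate_Hz) >= 0))
  expect_false(is.na(fi$rheobase))
  below <- fi$curve$I < fi$rheobase
  expect_true(all(fi$curve$rate_Hz[below] == 0))
  expect_gt(fi$curve$rate_Hz[fi$curve$I == fi$rheobase], 0)

  # basket-like cell at 430 pA for 500 ms: fires at a finite rate
  out <- izhikevich_integrate(p, 430, dt = 0.1, T = 500)
  expect_gt(length(out$train$times), 0L)
  expect_true(is.finite(length(out$train$times) / 0.5))
})

test_that("rheobase decreases as the threshold approaches rest", {
  near <- izhikevich_params(C = 100, k = 0.7, v_r = -60, v_t = -50,
                            v_peak = 35, v_min = -50, a = 0.03, b = -2,
                            d = 100)
  far <- izhikevich_preset("regular_spiking")  # v_t = -40
  rhe_near <- f_i_curve(near, 0, 300, 10, duration = 500)$rheobase
  rhe_far <- f_i_curve(far, 0, 300, 10, duration = 500)$rheobase
  expect_lt(rhe_near, rhe_far)
})

test_that("extracted features match hand computation on known traces", {
  p <- izhikevich_preset("regular_spiking")
  silent <- izhikevich_integrate(p, 0, dt = 0.1, T = 300)
  f0 <- extract_features(silent)
  expect_equal(f0$V_rest, p$v_r)
  expect_equal(f0$mean_rate, 0)
  expect_equal(f0$n_spikes, 0L)

  # constant-ISI synthetic train: rate and adaptation by hand
  tr <- list(t = seq(0, 1000, by = 0.1),
             v = rep(p$v_r, 10001L),
             train = spike_train(seq(100, 1000, by = 100),
                                 stim_window = c(0, 1000), dt = 0.1,
                                 T = 1000))
  f1 <- extract_features(tr)
  expect_equal(f1$mean_rate, 10)      # 10 spikes / 1 s
  expect_equal(f1$max_rate, 10)       # min ISI = 100 ms
  expect_equal(f1$adaptation_ratio, 1.0)
  expect_equal(f1$latency, 100)

  real <- izhikevich_integrate(p, 150, dt = 0.1, T = 1000)
  f2 <- extract_features(real)
  expect_equal(f2$n_spikes, length(real$train$times))
  expect_equal(f2$mean_rate, length(real$train$times) / 1)
  expect_gt(f2$adaptation_ratio, 1)   # RS archetype adapts
  expect_gt(f2$AP_ampl, 60)
})

test_that("firing-pattern labels follow the documented ISI rules", {
  win <- c(0, 1000)
  lab <- function(times) classify_firing_pattern(
    spike_train(times, stim_window = win, T = 1000))

  expect_equal(lab(numeric(0)), "SLN")
  expect_equal(lab(seq(50, 950, length.out = 10)), "NASP")

  # ISIs growing by 20% each step: last/first well above 1.3
  isis <- 30 * 1.2^(0:9)
  expect_equal(lab(cumsum(c(20, isis))), "ASP.")

  # burst confined to the first 20% then silence
  expect_equal(lab(c(20, 40, 60, 80, 100)), "TSTUT.SLN")

  # clusters only after the transient window: persistent stuttering
  pstut <- c(seq(300, 340, by = 10), seq(600, 640, by = 10),
             seq(900, 940, by = 10))
  expect_equal(lab(pstut), "PSTUT")

  # early burst, then persistent gaps
  tstut_pstut <- c(seq(10, 60, by = 10), seq(400, 440, by = 10),
                   seq(800, 840, by = 10))
  expect_equal(lab(tstut_pstut), "TSTUT.PSTUT")

  # gap confined to the transient window, steady afterwards
  tstut <- c(0, 50, 100, seq(400, 1000, by = 50))
  expect_equal(lab(tstut), "TSTUT.")
})

test_that("sub-ISI jitter never flips NASP and SLN into each other", {
  set.seed(21)
  win <- c(0, 1000)
  for (rep in 1:10) {
    base <- seq(50, 950, length.out = 12) + runif(12, -1, 1)
    med_isi <- median(diff(base))
    jit <- sort(base + runif(12, -0.009, 0.009) * med_isi)
    l1 <- classify_firing_pattern(spike_train(base, win, T = 1000))
    l2 <- classify_firing_pattern(spike_train(jit, win, T = 1000))
    expect_false(xor(l1 == "SLN", l2 == "SLN"))
    expect_equal(l1 == "NASP", l2 == "NASP")
  }
  expect_equal(classify_firing_pattern(spike_train(numeric(0), win)), "SLN")
})
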