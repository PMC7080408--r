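test_that("the intercept of the cumulative-charge fit equals the depleted pool", {
  n0 <- 3000; p <- 0.2
  q <- quantal_charge(pA(20))
  dtr <- depletion_train_trace(n0, p)
  ta <- analyze_train(dtr$trace, dtr$protocol, q)
  expect_false(ta$flagged)
  expect_equal(ta$fit_intercept, n0 * q, tolerance = 0.005)
  expect_lt(abs(ta$fit_slope), 0.001 * n0 * q)
  expect_equal(ta$pvr_train, p, tolerance = 0.01)
  expect_equal(ta$rrp_vesicles, n0, tolerance = 0.005)
  # analytic per-stimulus series: Q_i = q N0 p (1-p)^(i-1)
  i <- seq_len(10)
  expect_equal(ta$per_stimulus_charge[i], q * n0 * p * (1 - p)^(i - 1),
               tolerance = 0.01)
  expect_true(all(diff(ta$cumulative_charge) >= 0))
})

test_that("a simulated train without replenishment plateaus at the pool charge", {
  p <- synapse_params(n_rrp = 3000, p_vr = 0.2, k_spont = 0, k_async = 0,
                      k_replenish = 0, noise_sd = pA(4))
  q <- quantal_charge(p$q_amp)
  aps <- 0.2 + (0:79) / 50
  prot <- stim_protocol(ap_times = aps, train = list(frequency = 50, count = 80))
  sim <- simulate_evoked(p, prot, duration = max(aps) + 0.3, seed = 51)
  ta <- analyze_train(sim$bundle$traces$s1, prot, q)
  expect_equal(ta$fit_intercept, p$n_rrp * q, tolerance = 0.1)
  expect_lt(abs(ta$fit_slope) * 20, 0.05 * ta$fit_intercept)
})

test_that("the replenishment rate constant is recovered from 50 Hz trains", {
  p <- synapse_params(n_rrp = 3000, p_vr = 0.2, k_spont = 0, k_async = 0,
                      k_replenish = 0.6, noise_sd = pA(4))
  q <- quantal_charge(p$q_amp)
  aps <- 0.2 + (0:79) / 50
  prot <- stim_protocol(ap_times = aps, train = list(frequency = 50, count = 80))
  est <- vapply(1:20, function(s) {
    sim <- simulate_evoked(p, prot, duration = max(aps) + 0.3, seed = 600 + s)
    analyze_train(sim$bundle$traces$s1, prot, q)$replenishment_rate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6) / 0.6, 0.25)
})

test_that("replenishment rate is invariant to quantal-size rescaling", {
  dtr <- depletion_train_trace(3000, 0.2, q_amp = pA(20))
  dtr2 <- depletion_train_trace(3000, 0.2, q_amp = pA(40))
  r1 <- analyze_train(dtr$trace, dtr$protocol)$replenishment_rate
  r2 <- analyze_train(dtr2$trace, dtr2$protocol)$replenishment_rate
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("the depletion correction scales the pool by the charge ratio", {
  # construct a 10 Hz train whose last/first charge ratio is known, with a
  # pure fast response (no asynchronous component): k ~ 0
  p <- synapse_params(n_rrp = 3000, p_vr = 0.15, k_spont = 0, k_async = 0,
                      k_replenish = 0.5, noise_sd = pA(2))
  q <- quantal_charge(p$q_amp)
  aps <- 0.2 + (0:49) / 10
  prot <- stim_protocol(ap_times = aps, train = list(frequency = 10, count = 50))
  sim <- simulate_evoked(p, prot, duration = max(aps) + 0.3, seed = 61)
  k0 <- async_rate_train(sim$bundle$traces$s1, prot, q, p$n_rrp)
  expect_lt(k0, 0.1)
})

test_that("the asynchronous rate during a train matches the event-log oracle", {
  # moderate asynchronous load: the stated depletion correction
  # A* = n * Q_last/Q_first is only accurate while the last EPSC remains
  # dominated by its synchronous component
  p <- synapse_params(n_rrp = 3000, p_vr = 0.1, k_spont = 0, k_async = 0.05,
                      tau_async = 0.3, k_replenish = 0.5, noise_sd = pA(2))
  q <- quantal_charge(p$q_amp)
  aps <- 0.2 + (0:49) / 10
  prot <- stim_protocol(ap_times = aps, train = list(frequency = 10, count = 50))
  est <- numeric(0); oracle <- numeric(0)
  for (s in 1:10) {
    sim <- simulate_evoked(p, prot, duration = max(aps) + 0.3, seed = 700 + s)
    est[s] <- async_rate_train(sim$bundle$traces$s1, prot, q, p$n_rrp)
    t_last <- max(aps)
    n_async <- sum(sim$log$fusion_times > t_last &
                     sim$log$fusion_times <= t_last + 0.1 &
                     sim$log$fusion_mode == "asynchronous")
    n_bar <- mean(pool_at(sim$log, seq(t_last, t_last + 0.1, by = 0.01)))
    oracle[s] <- n_async / 0.1 / n_bar
  }
  expect_lt(abs(mean(est) - mean(oracle)) / mean(oracle), 0.3)
})

test_that("post-train spontaneous rate honors its window and recovers truth", {
  # window boundary: an event 50 ms after the train is excluded
  aps <- 0.2 + (0:9) / 10
  prot <- stim_protocol(ap_times = aps, train = list(frequency = 10, count = 10))
  t_last <- max(aps)
  set.seed(9)
  tr <- kernel_trace(c(t_last + 0.05, t_last + 0.2, t_last + 5),
                     duration = t_last + 10.2, noise_sd = pA(0.5))
  srr <- post_train_srr(tr, prot, n_rrp = 1000)
  expect_equal(srr, (2 / 10) / 1000, tolerance = 1e-3)
  expect_error(post_train_srr(trace_window(tr, c(0, t_last + 5)), prot, 1000),
               "10 s")

  p <- synapse_params(n_rrp = 1000, p_vr = 0.05, k_spont = 5e-3, k_async = 0,
                      k_replenish = 1, noise_sd = pA(4))
  sim <- simulate_evoked(p, prot, duration = t_last + 10.2, seed = 71)
  est <- post_train_srr(sim$bundle$traces$s1, prot, p$n_rrp)
  expect_lt(abs(est - p$k_spont) / p$k_spont, 0.2)
})
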