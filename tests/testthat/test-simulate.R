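test_that("simulation is reproducible under a seed", {
  p <- synapse_params(n_rrp = 1000, k_spont = 2e-3)
  a <- simulate_minis(p, duration = 5, seed = 99)
  b <- simulate_minis(p, duration = 5, seed = 99)
  expect_identical(a$bundle$traces$s1$samples, b$bundle$traces$s1$samples)
  expect_identical(a$log$fusion_times, b$log$fusion_times)
  c2 <- simulate_minis(p, duration = 5, seed = 100)
  expect_false(identical(a$bundle$traces$s1$samples,
                         c2$bundle$traces$s1$samples))
})

test_that("zero spontaneous rate yields a pure-noise sweep", {
  p <- synapse_params(n_rrp = 1000, k_spont = 0, noise_sd = pA(4))
  sim <- simulate_minis(p, duration = 10, seed = 1)
  expect_length(sim$log$fusion_times, 0)
  expect_lt(abs(mean(sim$bundle$traces$s1$samples)), pA(0.5))
})

test_that("spontaneous event counts match the Poisson mean", {
  p <- synapse_params(n_rrp = 5000, k_spont = 1e-3, noise_sd = 0)
  sim <- simulate_minis(p, duration = 100, seed = 7)
  n_ev <- length(sim$log$fusion_times)
  expect_lt(abs(n_ev - 500), 3 * sqrt(500))
})

test_that("pool conservation holds at all times in every protocol", {
  p <- synapse_params(n_rrp = 800, k_spont = 2e-3, p_vr = 0.2,
                      k_async = 0.1, k_replenish = 0.5)
  sims <- list(
    simulate_minis(p, duration = 20, seed = 2),
    simulate_evoked(p, stim_protocol(ap_times = seq(0.1, 0.9, by = 0.2)),
                    seed = 3),
    simulate_sucrose(p, duration = 8, window = c(1, 6), seed = 4))
  for (sim in sims) {
    log <- sim$log
    tt <- seq(0, max(log$fusion_times, 1), length.out = 500)
    N <- pool_at(log, tt)
    expect_true(all(N >= 0 & N <= log$n_rrp))
    # fused + remaining - replenished = n_rrp at the end of the sweep
    n_end <- pool_at(log, Inf)
    expect_identical(length(log$fusion_times) + n_end -
                       length(log$replenish_times), log$n_rrp)
  }
})

test_that("the rendered trace is the sum of quantal kernels at logged times", {
  p <- synapse_params(n_rrp = 500, k_spont = 3e-3, noise_sd = 0)
  sim <- simulate_minis(p, duration = 10, seed = 5)
  tr <- sim$bundle$traces$s1
  total_q <- integrate_charge(tr, c(0, 9.9), 0)
  expect_equal(total_q,
               sum(sim$log$fusion_times < 9.85) * quantal_charge(p$q_amp),
               tolerance = 0.02)
})

test_that("synchronous release is binomial in the available pool", {
  p <- synapse_params(n_rrp = 4000, p_vr = 0.15, k_spont = 0, k_async = 0,
                      k_replenish = 0, noise_sd = 0)
  sim <- simulate_evoked(p, stim_protocol(ap_times = 0.1), seed = 6)
  n_rel <- sum(sim$log$fusion_mode == "synchronous")
  expect_lt(abs(n_rel - 4000 * 0.15), 3 * sqrt(4000 * 0.15 * 0.85))
})

test_that("zero release probability gives a noise-only evoked sweep", {
  p <- synapse_params(n_rrp = 4000, p_vr = 0, k_async = 0, k_spont = 0,
                      noise_sd = pA(4))
  sim <- simulate_evoked(p, stim_protocol(ap_times = 0.1), seed = 8)
  q <- integrate_charge(sim$bundle$traces$s1, c(0.1, 0.5), c(0.05, 0.1))
  expect_lt(abs(q), 5 * pA(4) * sqrt(4000) * 1e-4)
})

test_that("sucrose depletes the whole pool when replenishment is off", {
  p <- synapse_params(n_rrp = 3000, k_replenish = 0, k_spont = 0,
                      noise_sd = 0)
  sim <- simulate_sucrose(p, duration = 9, window = c(2, 7), seed = 9)
  fused <- sum(sim$log$fusion_mode == "sucrose")
  expect_lt(abs(fused - 3000), 3 * sqrt(3000))
  # conservation of charge: transient charge / quantal charge ~ n_rrp
  q_tot <- integrate_charge(sim$bundle$traces$s1, c(2, 7), c(1, 2))
  expect_equal(q_tot / quantal_charge(p$q_amp), 3000, tolerance = 0.03)
})

test_that("the post-depletion sucrose fusion rate sits at the fixed point", {
  # dN/dt = 0 at N* = k_rep n/(k_suc + k_rep); fusion rate k_suc N*
  p <- synapse_params(n_rrp = 3000, k_replenish = 0.3, k_sucrose = 1.5,
                      k_spont = 0, noise_sd = 0)
  rate_exp <- p$k_replenish * p$n_rrp * p$k_sucrose /
    (p$k_sucrose + p$k_replenish)
  rates <- vapply(1:5, function(s) {
    sim <- simulate_sucrose(p, duration = 12, window = c(1, 11), seed = 20 + s)
    sum(sim$log$fusion_times > 6 & sim$log$fusion_times < 11) / 5
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - rate_exp), 3 * max(se, sqrt(rate_exp / 25)))
})

test_that("calcium series amplitudes follow the Hill factor", {
  expect_equal(hill_factor(0.94, 0.94, 1.92), 0.5)   # midpoint identity
  p <- synapse_params(n_rrp = 1e6, p_vr = 0.2, k_spont = 0, k_async = 0,
                      k_replenish = 0, noise_sd = 0)
  b <- simulate_ca_series(p, ca_list = c(0.5, 2, 4, 10), seed = 12)
  ids <- grep("^ca", names(b$traces), value = TRUE)
  cas <- vapply(ids, function(id) b$protocols[[id]]$ca_ext, numeric(1))
  amp <- vapply(ids, function(id) {
    tr <- b$traces[[id]]
    base <- baseline_level(tr, c(0.095, 0.1))
    base - min(trace_window(tr, c(0.102, 0.13))$samples)
  }, numeric(1))
  o <- order(cas)
  norm <- amp[o] / amp[o][4]
  hexp <- hill_factor(sort(cas), p$hill_ec50, p$hill_n) /
    hill_factor(10, p$hill_ec50, p$hill_n)
  expect_equal(norm, hexp, tolerance = 0.01, ignore_attr = TRUE)
  expect_true(all(diff(amp[o]) > 0))                 # monotone in calcium
})
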