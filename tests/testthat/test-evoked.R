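# synthetic EPSC: instantaneous rise at t_on, one or two exponential decays
exp_epsc <- function(amps, taus, t_on = 0.1, duration = 0.7, dt = 1e-4,
                     noise_sd = 0) {
  tt <- seq(0, duration - dt, by = dt)
  y <- numeric(length(tt))
  on <- tt >= t_on
  for (k in seq_along(amps))
    y[on] <- y[on] - amps[k] * exp(-(tt[on] - t_on) / taus[k])
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  trace(y, dt = dt)
}

test_that("a pure exponential EPSC is measured exactly", {
  tr <- exp_epsc(nA(2), 5e-3)
  m <- measure_eepsc(tr, 0.098, ap_duration = 2e-3)
  expect_false(m$fit_flagged)
  expect_equal(m$peak_amplitude, nA(2), tolerance = 0.01)
  expect_equal(m$fast_tau, 5e-3, tolerance = 0.02)
  expect_lt(m$async_charge / m$total_charge, 0.03)
})

test_that("fast and asynchronous charge split matches known component areas", {
  a <- c(nA(2), nA(0.05)); taus <- c(5e-3, 0.2)
  tr <- exp_epsc(a, taus)
  m <- measure_eepsc(tr, 0.098, window_end = 0.5)
  fast_true <- a[1] * taus[1]
  async_true <- a[2] * taus[2] * (1 - exp(-0.5 / taus[2]))
  expect_equal(m$fast_charge, fast_true, tolerance = 0.1)
  expect_equal(m$async_charge, async_true, tolerance = 0.1)
})

test_that("a flat sweep yields a flagged, near-zero measurement", {
  set.seed(2)
  tr <- trace(rnorm(7000, 0, pA(2)), dt = 1e-4)
  m <- measure_eepsc(tr, 0.098)
  expect_true(m$fit_flagged)
  expect_lt(m$peak_amplitude, pA(20))
})

test_that("deconvolving a scaled mini recovers the delta release", {
  mini <- quantal_kernel(pA(20))
  tr <- kernel_trace(0.1, duration = 0.7, scale = 500)
  rrw <- deconvolve_release_rate(tr, mini)
  expect_equal(rrw$cumulative[length(rrw$cumulative)], 500, tolerance = 0.02)
})

test_that("deconvolution round trip reconstructs the EPSC at SNR 20", {
  p <- synapse_params(n_rrp = 5000, p_vr = 0.1, k_async = 0.1,
                      noise_sd = 0)
  sim <- simulate_evoked(p, stim_protocol(ap_times = 0.1), seed = 31)
  clean <- sim$bundle$traces$s1$samples
  win <- 950:2100                               # response region
  sig_rms <- sqrt(mean(clean[win]^2))
  noise_sd <- sig_rms / 20                      # trace-level SNR 20
  set.seed(32)
  y <- clean + rnorm(length(clean), 0, noise_sd)
  tr <- trace(y, dt = 1e-4)
  mini <- quantal_kernel(p$q_amp)
  rrw <- deconvolve_release_rate(tr, mini, baseline_window = c(0.02, 0.09))
  # reconvolve the rates with the unit-charge mini
  q <- quantal_charge(p$q_amp)
  m_unit <- mini / (sum(mini) * 1e-4)
  nfft <- stats::nextn(length(y) + length(mini), 2)
  recon_n <- Re(stats::fft(stats::fft(c(rrw$rates, numeric(nfft - length(y)))) *
                           stats::fft(c(m_unit, numeric(nfft - length(m_unit)))),
                           inverse = TRUE)) / nfft * 1e-4
  recon <- -q * recon_n[seq_along(y)]
  rel_rms <- sqrt(mean((recon[win] - clean[win])^2)) / sig_rms
  expect_lt(rel_rms, 0.05)
  # vesicle count also survives the noise
  n_true <- length(sim$log$fusion_times)
  expect_equal(max(rrw$cumulative), n_true, tolerance = 0.1)
})

test_that("a boxcar release waveform is recovered with its plateau", {
  dt <- 1e-4
  rates <- numeric(5000)
  rates[1001:1020] <- 20000                     # 20 SV/ms for 2 ms
  ker <- quantal_kernel(pA(20))
  nfft <- stats::nextn(5000 + length(ker), 2)
  y <- Re(stats::fft(stats::fft(c(rates, numeric(nfft - 5000))) *
                     stats::fft(c(ker, numeric(nfft - length(ker)))),
                     inverse = TRUE))[1:5000] / nfft * dt
  tr <- trace(y, dt = dt)
  rrw <- deconvolve_release_rate(tr, ker)
  peak <- peak_release_rate(rrw, n_rrp = 1)     # SV/s over a 1 ms bin
  expect_equal(peak, 20000, tolerance = 0.1)
})

test_that("peak release rate is the max 1 ms slope over the pool", {
  rates <- c(numeric(100), rep(1e5, 50), numeric(100))  # 100 SV/ms for 5 ms
  rrw <- structure(list(rates = rates, dt = 1e-4, t0 = 0,
                        cumulative = cumsum(rates) * 1e-4),
                   class = "release_rates")
  expect_equal(peak_release_rate(rrw, 5000), 20)
  zero <- structure(list(rates = numeric(200), dt = 1e-4, t0 = 0,
                         cumulative = numeric(200)), class = "release_rates")
  expect_equal(peak_release_rate(zero, 5000), 0)
  expect_error(peak_release_rate(rrw, 0), "n_rrp")
})

test_that("deconvolved peak rate matches the ground-truth fusion histogram", {
  p <- synapse_params(n_rrp = 5000, p_vr = 0.1, k_async = 0.1,
                      noise_sd = pA(4))
  sim <- simulate_evoked(p, stim_protocol(ap_times = 0.1), seed = 33)
  rrw <- deconvolve_release_rate(sim$bundle$traces$s1, quantal_kernel(p$q_amp),
                                 baseline_window = c(0.02, 0.09))
  k_est <- peak_release_rate(rrw, p$n_rrp)
  h <- hist(sim$log$fusion_times, breaks = seq(0, 0.7, by = 1e-3),
            plot = FALSE)$counts
  k_oracle <- max(h) / 1e-3 / p$n_rrp
  expect_equal(k_est, k_oracle, tolerance = 0.2)
})

test_that("release probability is a scale-invariant ratio", {
  expect_equal(compute_pvr(500, 5000), 0.1)
  expect_equal(compute_pvr(0, 5000), 0)
  expect_equal(compute_pvr(1000, 10000), compute_pvr(500, 5000))
  expect_error(compute_pvr(500, 0), "n_rrp")
})

test_that("P_vr is recovered from simulated evoked sweeps", {
  p <- synapse_params(n_rrp = 5000, p_vr = 0.12, k_async = 0, k_spont = 0,
                      noise_sd = pA(4))
  q <- quantal_charge(p$q_amp)
  est <- vapply(1:20, function(s) {
    sim <- simulate_evoked(p, stim_protocol(ap_times = 0.1), seed = 300 + s)
    m <- measure_eepsc(sim$bundle$traces$s1, 0.1)
    compute_pvr(m$total_charge / q, p$n_rrp)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.12) / 0.12, 0.15)
})

test_that("identical paired responses give a PPR of one", {
  tr <- kernel_trace(c(0.1, 0.2), duration = 0.5, scale = 300,
                     noise_sd = pA(1))
  expect_equal(compute_ppr(tr, c(0.098, 0.198)), 1.0, tolerance = 0.02)
})

test_that("paired-pulse depression follows the depletion recursion", {
  # PPR -> 1 - p exp(-k_rep * isi); MC mean over seeds within 3 SE
  cases <- list(list(p = 0.3, k = 0, isi = 0.05),
                list(p = 0.3, k = 2, isi = 0.05),
                list(p = 0.4, k = 2, isi = 0.025))
  for (cs in cases) {
    pp <- synapse_params(n_rrp = 2000, p_vr = cs$p, k_async = 0, k_spont = 0,
                         k_replenish = cs$k, noise_sd = pA(2))
    aps <- c(0.1, 0.1 + cs$isi)
    set.seed(777)
    r <- vapply(1:120, function(s) {
      sim <- simulate_evoked(pp, stim_protocol(ap_times = aps), duration = 0.3)
      compute_ppr(sim$bundle$traces$s1, aps)
    }, numeric(1))
    expected <- 1 - cs$p * exp(-cs$k * cs$isi)
    se <- sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - expected), 3 * se + 0.003)
  }
})

test_that("the asynchronous rate after one stimulus is charge over window and pool", {
  m <- structure(list(async_charge = 50 * fC(80), fit_flagged = FALSE),
                 class = "evoked_metrics")
  expect_equal(async_rate_single(m, fC(80), 5000, window = 0.5), 0.02)
  m0 <- structure(list(async_charge = 0, fit_flagged = FALSE),
                  class = "evoked_metrics")
  expect_equal(async_rate_single(m0, fC(80), 5000), 0)
  expect_error(async_rate_single(m, 0, 5000), "mini_charge")
})

test_that("the asynchronous rate constant is recovered when tau_async spans the window", {
  p <- synapse_params(n_rrp = 5000, p_vr = 0.1, k_async = 0.1,
                      tau_async = 5, k_spont = 0, k_replenish = 0,
                      noise_sd = pA(4))
  q <- quantal_charge(p$q_amp)
  est <- vapply(1:20, function(s) {
    sim <- simulate_evoked(p, stim_protocol(ap_times = 0.1), seed = 400 + s)
    m <- measure_eepsc(sim$bundle$traces$s1, 0.1, window_end = 0.5)
    async_rate_single(m, q, p$n_rrp, window = 0.5)
  }, numeric(1))
  expect_lt(abs(mean(est) - p$k_async) / p$k_async, 0.25)
})
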