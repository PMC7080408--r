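# Synthetic fixtures built in code: deterministic traces with known ground
# truth used across the test files.

# trace containing kernels at given times on a flat baseline plus optional
# white noise
kernel_trace <- function(times, q_amp = pA(20), duration = 1, dt = 1e-4,
                         noise_sd = 0, tau_rise = 0.5e-3, tau_decay = 3e-3,
                         scale = 1) {
  n <- round(duration / dt)
  y <- numeric(n)
  ker <- quantal_kernel(q_amp, tau_rise, tau_decay, dt) * scale
  for (t in times) {
    i <- round(t / dt) + 1L
    j <- min(i + length(ker) - 1L, n)
    if (i <= n) y[i:j] <- y[i:j] + ker[seq_len(j - i + 1L)]
  }
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  trace(y, dt = dt)
}

# ideal RC charging response to a current step
rc_trace <- function(r = 250e6, tau = 25e-3, step_current = -pA(20),
                     step_window = c(0.2, 0.7), duration = 1, dt = 1e-4,
                     v_rest = mV(-70), noise_sd = 0) {
  tt <- seq(0, duration - dt, by = dt)
  dv <- r * step_current
  v <- v_rest +
    ifelse(tt >= step_window[1] & tt < step_window[2],
           dv * (1 - exp(-(tt - step_window[1]) / tau)),
           ifelse(tt >= step_window[2],
                  dv * (1 - exp(-diff(step_window) / tau)) *
                    exp(-(tt - step_window[2]) / tau), 0))
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  trace(v, dt = dt, role = "cc_voltage")
}

# current-clamp sweep with one action potential: slow 2 mV/ms foot up to the
# constructed inflection voltage, then a fast upstroke to the peak
ap_trace <- function(threshold = mV(-38), peak = mV(35), v_rest = mV(-70),
                     t_ap = 0.3, duration = 0.6, dt = 1e-4, noise_sd = 0) {
  tt <- seq(0, duration - dt, by = dt)
  v <- rep(v_rest, length(tt))
  i0 <- which(tt >= t_ap)[1]
  foot <- seq(v_rest, threshold, by = mV(0.2))
  up <- seq(threshold, peak, length.out = 8)
  down <- seq(peak, v_rest, length.out = 41)
  shape <- c(foot, up[-1], down[-1])
  v[i0:(i0 + length(shape) - 1L)] <- shape
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  trace(v, dt = dt, role = "cc_voltage")
}

# small multi-sweep bundle exercising every protocol field
demo_bundle <- function() {
  tr1 <- trace(sin(seq_len(500)) * pA(5), dt = 1e-4)
  tr2 <- trace(cos(seq_len(500)) * pA(5), dt = 1e-4)
  tr3 <- trace(rep(mV(-70), 500), dt = 1e-4, role = "cc_voltage")
  recording_bundle(
    traces = list(a = tr1, b = tr2, c = tr3),
    protocols = list(
      a = stim_protocol(ap_times = c(0.01, 0.03), ca_ext = 4),
      b = stim_protocol(sucrose_window = c(0.005, 0.04), ttx_present = TRUE),
      c = stim_protocol(train = list(frequency = 50, count = 80),
                        ap_times = seq(0.001, 0.04, by = 0.02),
                        negative_control = TRUE)),
    metadata = list(neuron_id = "n01", group = "Con", culture = "c1"))
}

# deterministic depletion train: at stimulus i the response is
# q_amp-scaled kernels for N_i * p vesicles, N_{i+1} = N_i (1 - p)
depletion_train_trace <- function(n0 = 3000, p = 0.2, freq = 50, count = 80,
                                  t_start = 0.2, q_amp = pA(20), dt = 1e-4,
                                  tail = 0.3) {
  isi <- 1 / freq
  duration <- t_start + count * isi + tail
  n <- round(duration / dt)
  y <- numeric(n)
  ker <- quantal_kernel(q_amp, dt = dt)
  N <- n0
  aps <- t_start + (seq_len(count) - 1L) * isi
  for (t in aps) {
    i <- round(t / dt) + 1L
    j <- min(i + length(ker) - 1L, n)
    y[i:j] <- y[i:j] + ker[seq_len(j - i + 1L)] * N * p
    N <- N * (1 - p)
  }
  list(trace = trace(y, dt = dt),
       protocol = stim_protocol(ap_times = aps,
                                train = list(frequency = freq, count = count)))
}
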