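#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (`signal::filtfilt`) so
#' that event latencies are not shifted.  DC gain is 1 and the trace length
#' is preserved.
#'
#' @param trace A [trace()].
#' @param cutoff Cut-off frequency in Hz; must be below Nyquist.
#' @param order Filter order of the one-way Butterworth design (default 4;
#'   the forward-backward pass squares the magnitude response).
#' @return A filtered [trace()].
#' @export
lowpass_filter <- function(trace, cutoff, order = 4) {
  stopifnot(inherits(trace, "trace"))
  nyq <- 0.5 / trace$dt
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must be in (0, %g) Hz (Nyquist)", nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  # filtfilt is applied to the mean-subtracted signal to avoid start-up
  # transients on traces with a large DC offset
  m <- mean(trace$samples)
  y <- signal::filtfilt(bf, trace$samples - m) + m
  trace(y, dt = trace$dt, role = trace$role, t0 = trace$t0)
}

#' Baseline level of a trace over a window
#'
#' @param trace A [trace()].
#' @param window `c(start, end)` seconds (absolute time).
#' @return Mean sample value over the window (SI units of the trace).
#' @export
baseline_level <- function(trace, window) {
  mean(trace_window(trace, window)$samples)
}

#' Charge transfer over a window
#'
#' Trapezoidal integral of the baseline-subtracted current over `window`.
#' By the sign convention used throughout the package, inward (negative)
#' currents yield positive charge magnitudes, so the returned value is
#' `-integral(I - I_baseline)`.
#'
#' @param trace A [trace()] with role `vc_current`.
#' @param window `c(start, end)` seconds; integration window.
#' @param baseline_window `c(start, end)` seconds over which the baseline
#'   current is averaged, or a precomputed numeric baseline level (A).
#' @return Charge in coulombs (positive for net inward current).
#' @export
integrate_charge <- function(trace, window, baseline_window) {
  stopifnot(inherits(trace, "trace"))
  base <- if (is.numeric(baseline_window) && length(baseline_window) == 1L)
    baseline_window else baseline_level(trace, baseline_window)
  seg <- trace_window(trace, window)$samples - base
  n <- length(seg)
  -(sum(seg) - 0.5 * (seg[1] + seg[n])) * trace$dt
}

#' Biexponential quantal kernel
#'
#' Difference-of-exponentials waveform
#' `q * (exp(-t/tau_decay) - exp(-t/tau_rise))`, normalized so that its peak
#' equals `-q_amp` (inward current), sampled on a grid of step `dt`.  This is
#' the postsynaptic current generated by fusion of a single vesicle, and the
#' same shape serves as the detection template for miniature events.
#'
#' @param q_amp Peak amplitude magnitude in A.
#' @param tau_rise Rise time constant (s), default 0.5 ms.
#' @param tau_decay Decay time constant (s), default 3 ms.
#' @param dt Sampling interval (s).
#' @param duration Kernel support (s); default `tau_rise + 8 * tau_decay`.
#' @return Numeric vector of current samples (A), first sample at t = 0.
#' @section Analytic area:
#' The charge of the kernel is `q_peak_scale * q_amp * (tau_decay - tau_rise)`
#' where `q_peak_scale` normalizes the raw difference of exponentials to unit
#' peak; see [quantal_charge()].
#' @export
quantal_kernel <- function(q_amp = pA(20), tau_rise = 0.5e-3,
                           tau_decay = 3e-3, dt = 1e-4,
                           duration = tau_rise + 8 * tau_decay) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  tt <- seq(0, duration, by = dt)
  raw <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  -q_amp * raw / .biexp_peak(tau_rise, tau_decay)
}

# peak value of exp(-t/td) - exp(-t/tr)
.biexp_peak <- function(tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' Analytic charge of the quantal kernel
#'
#' Closed-form magnitude of the charge carried by one [quantal_kernel()]:
#' `q_amp * (tau_decay - tau_rise) / peak_factor`.
#'
#' @inheritParams quantal_kernel
#' @return Charge magnitude in coulombs.
#' @export
quantal_charge <- function(q_amp = pA(20), tau_rise = 0.5e-3, tau_decay = 3e-3) {
  q_amp * (tau_decay - tau_rise) / .biexp_peak(tau_rise, tau_decay)
}
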