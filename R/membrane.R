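#' Passive membrane properties from a hyperpolarizing current step
#'
#' Input resistance comes from the steady-state voltage deflection
#' (`R_in = dV_ss / dI`), the membrane time constant from a single
#' exponential fit to the charging transient, and the capacitance from
#' `C = tau / R_in`.
#'
#' @param trace A [trace()] with role `cc_voltage`.
#' @param step_current Injected current (A); default -20 pA.
#' @param step_window `c(start, end)` (s) of the current step (0.5 s steps
#'   by convention).
#' @return An object of class `passive_props`: `resting_potential` (V),
#'   `input_resistance` (Ohm), `time_constant` (s), `capacitance` (F),
#'   `fit_flagged`.
#' @export
passive_properties <- function(trace, step_current = -pA(20), step_window) {
  stopifnot(inherits(trace, "trace"))
  if (step_current == 0) stop("step_current must be nonzero")
  t0 <- step_window[1]; t1 <- step_window[2]
  rest <- baseline_level(trace, c(max(trace$t0, t0 - 0.1), t0))
  v_ss <- baseline_level(trace, c(t1 - 0.2 * (t1 - t0), t1))
  dv <- v_ss - rest
  r_in <- dv / step_current
  seg <- trace_window(trace, c(t0, t1))
  tt <- trace_times(seg) - t0
  rel <- (seg$samples - v_ss) / (rest - v_ss)   # 1 -> 0 as the cell charges
  pos <- which(rel > 0.01 & tt > 0)
  flagged <- FALSE
  tau <- NA_real_
  if (length(pos) >= 5L) {
    lf <- stats::lm(log(rel[pos]) ~ tt[pos])
    tau0 <- -1 / stats::coef(lf)[[2]]
    fit <- tryCatch(
      stats::nls(v ~ v_ss + (rest - v_ss) * exp(-t / tau),
                 data = list(v = seg$samples, t = tt, v_ss = v_ss, rest = rest),
                 start = list(tau = max(tau0, 1e-4))),
      error = function(e) NULL)
    if (!is.null(fit)) tau <- stats::coef(fit)[["tau"]]
    else { tau <- tau0; flagged <- TRUE }
  } else flagged <- TRUE
  structure(list(resting_potential = rest, input_resistance = r_in,
                 time_constant = tau, capacitance = tau / r_in,
                 delta_v = dv, fit_flagged = flagged),
            class = "passive_props")
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf(
    "<passive_props> Vrest %.3g mV, Rin %.3g MOhm, tau %.3g ms, C %.3g pF%s\n",
    to_mV(x$resting_potential), x$input_resistance / 1e6,
    to_ms(x$time_constant), x$capacitance * 1e12,
    if (x$fit_flagged) " [fit flagged]" else ""))
  invisible(x)
}

#' Action potential threshold and amplitude
#'
#' Analyzes the first action potential inside `depol_window`.  The
#' threshold is the membrane potential at the inflection point of the
#' rising phase, operationalized as the maximum of the second time
#' derivative of the low-pass-smoothed rising phase; alternatively a
#' dV/dt-crossing criterion (default 10 mV/ms) can be chosen.  Amplitude is
#' peak minus threshold.
#'
#' @param trace A [trace()] with role `cc_voltage`.
#' @param depol_window `c(start, end)` (s) of the depolarizing step.
#' @param method `"inflection"` (max d2V/dt2) or `"dvdt"` (first crossing of
#'   `dvdt_criterion`).
#' @param dvdt_criterion Slope criterion for `method = "dvdt"` (V/s; 10
#'   mV/ms = 10).
#' @param smooth_cutoff Smoothing bandwidth (Hz) applied before
#'   differentiation; `NULL` for none.
#' @return List with `threshold` (V), `amplitude` (V), `peak` (V),
#'   `peak_time` (s).
#' @export
ap_metrics <- function(trace, depol_window, method = c("inflection", "dvdt"),
                       dvdt_criterion = 10, smooth_cutoff = 2000) {
  stopifnot(inherits(trace, "trace"))
  method <- match.arg(method)
  seg <- trace_window(trace, depol_window)
  if (!is.null(smooth_cutoff) && smooth_cutoff < 0.5 / seg$dt)
    seg <- lowpass_filter(seg, smooth_cutoff)
  v <- seg$samples; tt <- trace_times(seg); dt <- seg$dt
  dv <- c(diff(v), 0) / dt
  # first sample where the upstroke is steep and a peak follows
  up <- which(dv > max(dvdt_criterion, 5))
  if (!length(up)) stop("no action potential detected in the window")
  start <- up[1]
  after <- start + which(dv[start:length(dv)] <= 0) - 1L
  if (!length(after)) stop("no AP peak found after the upstroke")
  ipk <- after[1]
  peak <- v[ipk]
  # rising-phase segment: from the last slow point before the upstroke
  slow <- which(dv[seq_len(start)] < 1)
  i0 <- if (length(slow)) max(slow) else 1L
  rise <- i0:ipk
  thr <- if (method == "inflection") {
    d2 <- diff(dv[rise]) / dt
    imax_dv <- which.max(dv[rise])
    lim <- max(imax_dv - 1L, 2L)
    v[rise[which.max(d2[seq_len(lim)])]]
  } else {
    cross <- rise[dv[rise] >= dvdt_criterion]
    v[cross[1]]
  }
  list(threshold = thr, amplitude = peak - thr, peak = peak,
       peak_time = tt[ipk])
}
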