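#' Cumulative-charge analysis of a high-frequency stimulus train
#'
#' Implements the train-based RRP estimate: per-stimulus EPSC charges are
#' integrated over each inter-stimulus interval against the pre-train
#' baseline (so that asynchronous build-up is included), the cumulative
#' charge is plotted against stimulus number, and a straight line is fit to
#' the last 20 stimuli.  The y-intercept of that line is the RRP_train, the
#' slope is the steady-state replenishment charge per stimulus, the
#' replenishment rate constant is `slope * frequency / intercept`, and the
#' train release probability is the first-stimulus charge over the
#' intercept.
#'
#' @param trace A [trace()] with the train response (artifacts blanked).
#' @param protocol A [stim_protocol()] whose `train` and `ap_times` describe
#'   the stimulation (count >= 25 so that 20 late stimuli exist past the
#'   transient).
#' @param mean_mini_charge Optional mean mEPSC charge (C) used to express
#'   the RRP in vesicles.
#' @param n_fit Number of final stimuli in the linear fit (default 20).
#' @return An object of class `train_analysis`: `per_stimulus_charge`,
#'   `cumulative_charge` (C), `fit_slope` (C/stimulus), `fit_intercept`
#'   (C, the RRP_train), `rrp_vesicles` (if `mean_mini_charge` given),
#'   `pvr_train`, `replenishment_rate` (1/s), `flagged`.
#' @export
analyze_train <- function(trace, protocol, mean_mini_charge = NULL,
                          n_fit = 20L) {
  stopifnot(inherits(trace, "trace"), inherits(protocol, "stim_protocol"))
  if (is.null(protocol$train)) stop("protocol has no train specification")
  aps <- protocol$ap_times
  if (length(aps) < n_fit + 5L)
    stop(sprintf("train analysis needs at least %d stimuli", n_fit + 5L))
  isi <- 1 / protocol$train$frequency
  base <- baseline_level(trace, c(aps[1] - 5e-3, aps[1]))
  q_i <- vapply(aps, function(t0)
    integrate_charge(trace, c(t0, t0 + isi), base), numeric(1))
  cum <- cumsum(q_i)
  idx <- seq_along(aps)
  late <- idx > length(aps) - n_fit
  fit <- stats::lm(cum[late] ~ idx[late])
  intercept <- stats::coef(fit)[[1]]
  slope <- stats::coef(fit)[[2]]
  flagged <- !is.finite(intercept) || intercept <= 0
  structure(list(per_stimulus_charge = q_i, cumulative_charge = cum,
                 fit_slope = slope, fit_intercept = intercept,
                 rrp_vesicles = if (!is.null(mean_mini_charge))
                   intercept / mean_mini_charge else NA_real_,
                 pvr_train = if (!flagged) q_i[1] / intercept else NA_real_,
                 replenishment_rate = if (!flagged)
                   slope * protocol$train$frequency / intercept else NA_real_,
                 frequency = protocol$train$frequency,
                 flagged = flagged),
            class = "train_analysis")
}

#' @export
print.train_analysis <- function(x, ...) {
  cat(sprintf(
    "<train_analysis> %d stimuli @ %g Hz: RRP_train %.3g pC, Pvr %.3g, replenishment %.3g /s%s\n",
    length(x$per_stimulus_charge), x$frequency, to_pC(x$fit_intercept),
    x$pvr_train, x$replenishment_rate,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
plot.train_analysis <- function(x, ...) {
  idx <- seq_along(x$cumulative_charge)
  graphics::plot(idx, to_pC(x$cumulative_charge), xlab = "stimulus #",
                 ylab = "cumulative charge (pC)", ...)
  graphics::abline(a = to_pC(x$fit_intercept),
                   b = to_pC(x$fit_slope), lty = 2)
  invisible(x)
}

#' Asynchronous release rate constant during a train
#'
#' For the last EPSC of a 10 Hz train: a single exponential is fit to its
#' fast decay (baselined to the pre-train baseline), the fast component is
#' subtracted from the total charge of the final inter-stimulus interval,
#' and the residual is converted to vesicles per second.  To account for
#' pool depletion during the train, the remaining pool is estimated as
#' `A* = n_rrp * Q_last / Q_first` (a correction that may understate
#' depletion if release probability grows during the train); the rate
#' constant is the asynchronous vesicle rate divided by `A*`.
#'
#' @param trace A [trace()] with the train response.
#' @param protocol [stim_protocol()] with the train (default use: 50
#'   stimuli at 10 Hz).
#' @param mean_mini_charge Mean mEPSC charge (C), > 0.
#' @param n_rrp Vesicles in the RRP at rest.
#' @return Rate constant (1/s per vesicle).
#' @export
async_rate_train <- function(trace, protocol, mean_mini_charge, n_rrp) {
  stopifnot(inherits(trace, "trace"), inherits(protocol, "stim_protocol"))
  if (is.null(protocol$train)) stop("protocol has no train specification")
  if (mean_mini_charge <= 0) stop("mean_mini_charge must be > 0")
  aps <- protocol$ap_times
  isi <- 1 / protocol$train$frequency
  base <- baseline_level(trace, c(aps[1] - 5e-3, aps[1]))
  t_last <- aps[length(aps)]
  q_first <- integrate_charge(trace, c(aps[1], aps[1] + isi), base)
  q_last <- integrate_charge(trace, c(t_last, t_last + isi), base)
  if (q_first <= 0) stop("first-EPSC charge is not positive")
  a_star <- n_rrp * q_last / q_first
  tt <- trace_times(trace)
  v <- trace$samples - base
  s <- tt >= t_last + protocol$ap_duration &
    tt <= t_last + protocol$ap_duration + 0.015
  ipk <- which(s)[which.min(v[s])]
  dec <- tt >= tt[ipk] & tt < t_last + isi
  fast <- .fit_fast_decay(tt[dec] - tt[ipk], v[dec])
  fast_charge <- if (isTRUE(fast$ok))
    integrate_charge(trace, c(t_last, tt[ipk]), base) + fast$amp * fast$tau
  else NA_real_
  async_charge <- max(q_last - fast_charge, 0)
  (async_charge / mean_mini_charge) / isi / a_star
}

#' Spontaneous release rate constant after a train
#'
#' Runs the miniature-event detector on the 10 s window beginning 100 ms
#' after the last stimulus of the train and divides the resulting event
#' frequency by the RRP size.
#'
#' @param trace A [trace()] extending at least 10.1 s past the last
#'   stimulus.
#' @param protocol [stim_protocol()] with the train.
#' @param n_rrp Vesicles in the RRP.
#' @param ... Passed to [detect_events()].
#' @return Rate constant (1/s per vesicle).
#' @export
post_train_srr <- function(trace, protocol, n_rrp, ...) {
  stopifnot(inherits(trace, "trace"), inherits(protocol, "stim_protocol"))
  t_last <- max(protocol$ap_times)
  win <- c(t_last + 0.1, t_last + 10.1)
  if (win[2] > max(trace_times(trace)) + trace$dt / 2)
    stop("trace does not cover 10 s beginning 100 ms after the last stimulus")
  ev <- detect_events(trace_window(trace, win), ...)
  compute_srr(ev$frequency, n_rrp)
}
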