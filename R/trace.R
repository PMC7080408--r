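#' Uniformly sampled recording trace
#'
#' A trace is the basic container for one sweep of a whole-cell recording:
#' a uniformly sampled vector of current (A) or voltage (V) with its sampling
#' interval.  All internal units are SI; use [pA()], [mV()], [ms()] and
#' friends to convert reported values to the conventional units.
#'
#' @param samples Numeric vector, current in amperes (`role = "vc_current"`)
#'   or membrane potential in volts (`role = "cc_voltage"`).  Must be finite
#'   and of length >= 2.
#' @param dt Sampling interval in seconds (default `1e-4`, i.e. 10 kHz).
#' @param role `"vc_current"` or `"cc_voltage"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `trace` with fields `samples`, `dt`, `role`,
#'   `t0`.
#' @examples
#' tr <- trace(rnorm(1000, sd = 5e-12))
#' tr
#' @export
trace <- function(samples, dt = 1e-4, role = c("vc_current", "cc_voltage"),
                  t0 = 0) {
  role <- match.arg(role)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number of seconds")
  structure(list(samples = samples, dt = dt, role = role, t0 = t0),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s: %d samples @ %.6g kHz, %.4g s (t0 = %g s)\n",
              x$role, length(x$samples), 1e-3 / x$dt,
              length(x$samples) * x$dt, x$t0))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' Sample times of a trace
#' @param x A [trace()].
#' @return Numeric vector of times (s), same length as the trace.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' Extract a time window of a trace
#'
#' @param x A [trace()].
#' @param window `c(start, end)` in seconds (absolute time, i.e. comparable
#'   to `t0`).  Samples with `start <= t < end` are kept.
#' @return A new `trace` with `t0` set to the first retained sample time.
#' @export
trace_window <- function(x, window) {
  stopifnot(inherits(x, "trace"), length(window) == 2L)
  tt <- trace_times(x)
  keep <- which(tt >= window[1] & tt < window[2])
  if (length(keep) < 2L)
    stop(sprintf("window [%g, %g] s falls outside the trace", window[1], window[2]))
  trace(x$samples[keep], dt = x$dt, role = x$role, t0 = tt[keep[1]])
}

#' @export
plot.trace <- function(x, ..., unit = if (x$role == "vc_current") "pA" else "mV") {
  scale <- if (unit == "pA") 1e12 else if (unit == "nA") 1e9 else 1e3
  graphics::plot(trace_times(x), x$samples * scale, type = "l",
                 xlab = "time (s)", ylab = unit, ...)
  invisible(x)
}

#' Stimulus protocol attached to a sweep
#'
#' Describes the timed events applied during one sweep: somatic
#' action-potential commands, an optional hypertonic-sucrose application
#' window, an optional stimulus-train specification, and the recording
#' conditions (external calcium, TTX, kynurenic-acid negative control).
#'
#' @param ap_times Times (s) of AP-command onsets; strictly increasing.
#' @param ap_duration Duration (s) of the somatic depolarization command
#'   (default 2 ms); this window is treated as stimulus artifact.
#' @param sucrose_window Optional `c(start, end)` (s) of sucrose application.
#' @param train Optional `list(frequency = Hz, count = n)`; when present the
#'   `ap_times` are expected to be the train stimuli.
#' @param ca_ext External CaCl2 concentration in mM (default 2).
#' @param ttx_present Logical; TRUE for miniature-event sweeps in TTX.
#' @param negative_control Logical; TRUE for the kynurenic-acid sweep used to
#'   estimate detector false positives.
#' @param reference Logical; TRUE for interleaved standard-solution sweeps in
#'   the calcium dose-response protocol (stability check).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(ap_times = numeric(), ap_duration = 2e-3,
                          sucrose_window = NULL, train = NULL, ca_ext = 2,
                          ttx_present = FALSE, negative_control = FALSE,
                          reference = FALSE) {
  ap_times <- as.numeric(ap_times)
  if (length(ap_times) > 1L && any(diff(ap_times) <= 0))
    stop("ap_times must be strictly increasing")
  if (!is.null(sucrose_window)) {
    sucrose_window <- as.numeric(sucrose_window)
    if (length(sucrose_window) != 2L || sucrose_window[2] <= sucrose_window[1])
      stop("sucrose_window must be c(start, end) with end > start")
  }
  if (!is.null(train)) {
    if (is.null(train$frequency) || train$frequency <= 0)
      stop("train frequency must be > 0")
    if (is.null(train$count) || train$count < 2)
      stop("train count must be >= 2")
  }
  structure(list(ap_times = ap_times, ap_duration = ap_duration,
                 sucrose_window = sucrose_window, train = train,
                 ca_ext = ca_ext, ttx_present = isTRUE(ttx_present),
                 negative_control = isTRUE(negative_control),
                 reference = isTRUE(reference)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  bits <- c(
    if (length(x$ap_times)) sprintf("%d AP(s)", length(x$ap_times)),
    if (!is.null(x$train)) sprintf("train %g Hz x %d", x$train$frequency, x$train$count),
    if (!is.null(x$sucrose_window)) sprintf("sucrose [%g, %g] s",
                                            x$sucrose_window[1], x$sucrose_window[2]),
    sprintf("Ca %g mM", x$ca_ext),
    if (x$ttx_present) "TTX",
    if (x$negative_control) "KYN control",
    if (x$reference) "reference")
  cat("<stim_protocol>", paste(bits, collapse = ", "), "\n")
  invisible(x)
}

#' Bundle of sweeps from one recorded neuron
#'
#' Groups traces with their stimulus protocols plus free-form metadata
#' (neuron id, group label, culture id, ...).  Every sweep must have a
#' protocol and all sweeps must share the same sampling interval.
#'
#' @param traces Named list of [trace()] objects (names are sweep ids).
#' @param protocols Named list of [stim_protocol()] objects; names must match
#'   `traces`.
#' @param metadata Named list of scalar metadata.
#' @return An object of class `recording_bundle`.
#' @seealso [read_bundle()], [write_bundle()]
#' @export
recording_bundle <- function(traces, protocols, metadata = list()) {
  if (is.null(names(traces)) || any(names(traces) == ""))
    stop("traces must be a named list (sweep ids)")
  if (!setequal(names(traces), names(protocols)))
    stop("every sweep in 'traces' needs a matching entry in 'protocols'")
  dts <- vapply(traces, function(tr) tr$dt, numeric(1))
  if (max(dts) - min(dts) > 1e-12 * max(dts))
    stop("all sweeps in a bundle must share one sampling rate")
  structure(list(traces = traces, protocols = protocols[names(traces)],
                 metadata = metadata),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> %d sweep(s) @ %g kHz\n",
              length(x$traces), 1e-3 / x$traces[[1]]$dt))
  for (id in names(x$traces)) {
    cat(sprintf("  %s: %d samples; ", id, length(x$traces[[id]])))
    print(x$protocols[[id]])
  }
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}
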