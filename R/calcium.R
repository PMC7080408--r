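#' Assemble a calcium dose-response series from a bundle
#'
#' Measures the peak evoked amplitude of every non-reference sweep, averages
#' per external calcium concentration, and normalizes to the response at
#' the reference (10 mM) concentration.  Interleaved standard-solution
#' sweeps implement the stability rule: if any reference amplitude shifts
#' by more than `max_ref_shift` from the first one, the neuron is excluded.
#'
#' @param bundle A [recording_bundle()] whose sweeps carry `ca_ext` and the
#'   `reference` flag in their protocols (e.g. from [simulate_ca_series()]).
#' @param norm_ca Concentration used for normalization (mM, default 10).
#' @param max_ref_shift Allowed relative shift of the reference amplitude
#'   (default 0.2).
#' @return An object of class `ca_series`: `ca_mM`, `mean_amplitude` (A),
#'   `normalized`, `reference_amplitudes` (A), `excluded`.
#' @export
build_ca_series <- function(bundle, norm_ca = 10, max_ref_shift = 0.2) {
  stopifnot(inherits(bundle, "recording_bundle"))
  peak_of <- function(id) {
    tr <- bundle$traces[[id]]; p <- bundle$protocols[[id]]
    if (!length(p$ap_times)) return(NA_real_)
    t1 <- p$ap_times[1]
    base <- baseline_level(tr, c(t1 - 5e-3, t1))
    seg <- trace_window(tr, c(t1 + p$ap_duration, t1 + p$ap_duration + 0.03))
    max(base - min(seg$samples), 0)
  }
  is_ref <- vapply(bundle$protocols, function(p) p$reference, logical(1))
  ref_amps <- vapply(names(bundle$traces)[is_ref], peak_of, numeric(1))
  excluded <- length(ref_amps) > 1 &&
    any(abs(ref_amps - ref_amps[1]) / ref_amps[1] > max_ref_shift)
  ids <- names(bundle$traces)[!is_ref]
  cas <- vapply(ids, function(id) bundle$protocols[[id]]$ca_ext, numeric(1))
  amps <- vapply(ids, peak_of, numeric(1))
  ca_levels <- sort(unique(cas))
  mean_amp <- vapply(ca_levels, function(ca) mean(amps[cas == ca]), numeric(1))
  if (!any(abs(ca_levels - norm_ca) < 1e-9))
    stop(sprintf("no sweeps at the %g mM normalization concentration", norm_ca))
  ref <- mean_amp[which(abs(ca_levels - norm_ca) < 1e-9)]
  structure(list(ca_mM = ca_levels, mean_amplitude = mean_amp,
                 normalized = mean_amp / ref,
                 reference_amplitudes = unname(ref_amps),
                 excluded = excluded),
            class = "ca_series")
}

#' @export
print.ca_series <- function(x, ...) {
  cat("<ca_series>", if (x$excluded) "[EXCLUDED: reference shift > 20%]", "\n")
  print(data.frame(ca_mM = x$ca_mM, amplitude_nA = to_nA(x$mean_amplitude),
                   normalized = round(x$normalized, 4)), row.names = FALSE)
  invisible(x)
}

#' Fit the Hill equation to a calcium dose-response
#'
#' Least-squares fit of `A(c) = amax * c^n / (c^n + ec50^n)` to normalized
#' eEPSC amplitudes, returning the half-maximal concentration (EC50) and
#' the Hill coefficient with their standard errors.  `amax` is left free
#' because the normalization concentration need not be fully saturating.
#'
#' @param x A `ca_series` (from [build_ca_series()]) or a numeric vector of
#'   calcium concentrations (mM).
#' @param response Normalized amplitudes (required when `x` is numeric).
#' @param ... Unused.
#' @return An object of class `hill_fit`: `ec50` (mM), `hill_n`, `amax`,
#'   `se_ec50`, `se_n`, `out_of_range` (EC50 outside the tested
#'   concentrations), and the underlying `nls` fit.
#' @examples
#' ca <- c(0.5, 2, 4, 10)
#' resp <- hill_factor(ca, 0.94, 1.92) / hill_factor(10, 0.94, 1.92)
#' fit_hill(ca, resp)
#' @export
fit_hill <- function(x, response = NULL, ...) UseMethod("fit_hill")

#' @rdname fit_hill
#' @export
fit_hill.ca_series <- function(x, response = NULL, ...) {
  if (x$excluded) stop("series excluded by the reference-stability rule")
  fit_hill(x$ca_mM, x$normalized)
}

#' @rdname fit_hill
#' @export
fit_hill.default <- function(x, response = NULL, ...) {
  ca <- as.numeric(x)
  if (length(ca) < 4L)
    stop("Hill fit needs at least 4 concentrations")
  if (length(response) != length(ca)) stop("ca and response lengths differ")
  amax0 <- max(response)
  half <- amax0 / 2
  ord <- order(ca)
  ec0 <- tryCatch(stats::approx(response[ord], ca[ord], xout = half,
                                ties = mean)$y, error = function(e) NA_real_)
  if (!is.finite(ec0)) ec0 <- stats::median(ca)
  fit <- minpack.lm::nlsLM(
    response ~ amax * ca^n / (ca^n + ec50^n),
    data = data.frame(ca = ca, response = response),
    start = list(amax = amax0, ec50 = ec0, n = 2),
    lower = c(amax = 0.05, ec50 = 1e-3, n = 0.1),
    upper = c(amax = 10, ec50 = 100, n = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  if (!all(is.finite(stats::resid(fit)))) stop("Hill fit did not converge")
  structure(list(ec50 = cf[["ec50"]], hill_n = cf[["n"]], amax = cf[["amax"]],
                 se_ec50 = unname(se["ec50"]), se_n = unname(se["n"]),
                 out_of_range = cf[["ec50"]] < min(ca) || cf[["ec50"]] > max(ca),
                 ca = ca, response = response, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> EC50 = %.3g +/- %.2g mM, Hill n = %.3g +/- %.2g, amax = %.3g%s\n",
    x$ec50, x$se_ec50, x$hill_n, x$se_n, x$amax,
    if (x$out_of_range) " [EC50 outside tested range]" else ""))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill_n = object$hill_n, amax = object$amax)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  ca <- if (is.null(newdata)) object$ca
  else if (is.list(newdata)) newdata$ca else as.numeric(newdata)
  object$amax * hill_factor(ca, object$ec50, object$hill_n)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$ca, x$response, log = "x", xlab = "[Ca2+]ext (mM)",
                 ylab = "normalized eEPSC amplitude", ...)
  cc <- exp(seq(log(min(x$ca)), log(max(x$ca)), length.out = 100))
  graphics::lines(cc, predict(x, cc))
  invisible(x)
}
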