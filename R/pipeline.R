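#' Fusion-competent vesicles per synapse
#'
#' Divides the RRP vesicle count of a neuron by its synapse count, reported
#' to two decimals as in per-neuron summary tables.
#'
#' @param rrp_vesicles Vesicles in the RRP.
#' @param synapse_count Synapses per neuron, > 0.
#' @return SVs per synapse, rounded to 2 decimals.
#' @examples
#' vesicles_per_synapse(7145, 721)   # 9.91
#' @export
vesicles_per_synapse <- function(rrp_vesicles, synapse_count) {
  if (any(synapse_count <= 0)) stop("synapse_count must be > 0")
  round(rrp_vesicles / synapse_count, 2)
}

#' Analyze every protocol in a recording bundle
#'
#' Runs each applicable analysis stage on a per-neuron bundle and collects
#' the derived metrics in one summary: miniature-event detection with the
#' negative-control correction (TTX sweeps), sucrose RRP and replenishment,
#' single-AP evoked metrics, deconvolution peak release rate and P_vr,
#' paired-pulse ratios, train analysis, calcium series, and current-clamp
#' membrane properties.  Failed fits are flagged per metric, never dropped
#' silently.
#'
#' @param bundle A [recording_bundle()].
#' @param config Named list of stage options: `n_rrp` (override the RRP used
#'   for rate constants; default the sucrose estimate), `async_window` (s),
#'   `detect` (list passed to [detect_events()]).
#' @return An object of class `neuron_summary`: a named list of metrics in
#'   reporting units plus a `qc` list of flags.
#' @export
summarize_neuron <- function(bundle, config = list()) {
  stopifnot(inherits(bundle, "recording_bundle"))
  out <- list(neuron_id = bundle$metadata$neuron_id %||% NA,
              group = bundle$metadata$group %||% NA,
              culture = bundle$metadata$culture %||% NA)
  qc <- list()
  prot <- bundle$protocols
  det_args <- config$detect %||% list()

  mini_ids <- names(prot)[vapply(prot, function(p)
    p$ttx_present && !p$negative_control && is.null(p$sucrose_window), logical(1))]
  ctl_ids <- names(prot)[vapply(prot, function(p)
    p$ttx_present && p$negative_control, logical(1))]
  minis <- NULL
  if (length(mini_ids)) {
    minis <- do.call(detect_events, c(list(bundle$traces[[mini_ids[1]]]), det_args))
    if (length(ctl_ids)) {
      ctl <- do.call(detect_events, c(list(bundle$traces[[ctl_ids[1]]]), det_args))
      corr <- correct_false_positives(minis, ctl)
      qc$minis_discarded <- corr$discarded
      if (!corr$discarded) {
        out$mepsc_frequency_hz <- corr$corrected_frequency
        out$mepsc_amplitude_pa <- to_pA(corr$corrected_mean_amplitude)
        out$mepsc_charge_fc <- to_fC(corr$corrected_mean_charge)
      }
    } else {
      qc$minis_discarded <- FALSE
      out$mepsc_frequency_hz <- minis$frequency
      out$mepsc_amplitude_pa <- to_pA(minis$mean_amplitude)
      out$mepsc_charge_fc <- to_fC(minis$mean_charge)
    }
  }
  mini_q <- if (!is.null(out$mepsc_charge_fc)) fC(out$mepsc_charge_fc)
  else config$mean_mini_charge %||% NULL

  suc_ids <- names(prot)[vapply(prot, function(p)
    !is.null(p$sucrose_window), logical(1))]
  n_rrp <- config$n_rrp %||% NULL
  if (length(suc_ids) && !is.null(mini_q)) {
    p <- prot[[suc_ids[1]]]
    suc <- rrp_from_sucrose(bundle$traces[[suc_ids[1]]], p$sucrose_window, mini_q)
    qc$sucrose_flagged <- suc$flagged
    if (!suc$flagged) {
      out$rrp_suc_pc <- to_pC(suc$rrp_charge)
      out$rrp_suc_vesicles <- suc$rrp_vesicles
      out$replenishment_sucrose_s <- replenishment_from_steady_state(
        suc$steady_state_current, mini_q, suc$rrp_vesicles)
      out$sucrose_peak_rate_s <- sucrose_peak_rate(
        bundle$traces[[suc_ids[1]]], p$sucrose_window, mini_q, suc$rrp_vesicles)
      n_rrp <- n_rrp %||% suc$rrp_vesicles
    }
  }
  if (!is.null(minis) && !is.null(n_rrp) && !isTRUE(qc$minis_discarded)) {
    out$srr_per_s <- compute_srr(out$mepsc_frequency_hz %||% minis$frequency, n_rrp)
    out$dwell_time_s <- dwell_time(out$srr_per_s)
  }

  ev_ids <- names(prot)[vapply(prot, function(p)
    length(p$ap_times) == 1L && is.null(p$train) && !p$ttx_present &&
      !p$reference, logical(1))]
  if (length(ev_ids)) {
    aw <- config$async_window %||% 0.5
    avg <- average_traces(bundle$traces[ev_ids])
    ap <- prot[[ev_ids[1]]]$ap_times[1]
    met <- measure_eepsc(avg, ap, window_end = aw,
                         n_sweeps_averaged = length(ev_ids))
    qc$eepsc_flagged <- met$fit_flagged
    out$eepsc_peak_na <- to_nA(met$peak_amplitude)
    out$eepsc_fast_tau_ms <- to_ms(met$fast_tau)
    if (!is.null(mini_q) && !is.null(n_rrp)) {
      out$pvr <- compute_pvr(met$total_charge / mini_q, n_rrp)
      if (!met$fit_flagged)
        out$k_async_single_s <- async_rate_single(met, mini_q, n_rrp, aw)
      mini_ker <- quantal_kernel(pA(1), dt = avg$dt)   # shape only
      rrw <- deconvolve_release_rate(avg, mini_ker * (mini_q / quantal_charge(pA(1))),
                                     baseline_window = c(ap - 5e-3, ap))
      out$peak_release_rate_s <- peak_release_rate(rrw, n_rrp)
    }
  }

  pp_ids <- names(prot)[vapply(prot, function(p)
    length(p$ap_times) == 2L && is.null(p$train), logical(1))]
  if (length(pp_ids)) {
    out$ppr <- vapply(pp_ids, function(id) {
      p <- prot[[id]]
      tryCatch(compute_ppr(bundle$traces[[id]], p$ap_times, p$ap_duration),
               error = function(e) NA_real_)
    }, numeric(1))
    qc$ppr_flagged <- any(is.na(out$ppr))
  }

  tr_ids <- names(prot)[vapply(prot, function(p) !is.null(p$train), logical(1))]
  if (length(tr_ids)) {
    id <- tr_ids[1]
    ta <- analyze_train(bundle$traces[[id]], prot[[id]], mini_q)
    qc$train_flagged <- ta$flagged
    if (!ta$flagged) {
      out$rrp_train_pc <- to_pC(ta$fit_intercept)
      out$pvr_train <- ta$pvr_train
      out$replenishment_train_s <- ta$replenishment_rate
    }
  }

  cc_ids <- names(bundle$traces)[vapply(bundle$traces, function(tr)
    tr$role == "cc_voltage", logical(1))]
  if (length(cc_ids) && !is.null(config$step_window)) {
    pp <- passive_properties(bundle$traces[[cc_ids[1]]],
                             config$step_current %||% -pA(20),
                             config$step_window)
    qc$passive_flagged <- pp$fit_flagged
    out$input_resistance_mohm <- pp$input_resistance / 1e6
    out$time_constant_ms <- to_ms(pp$time_constant)
    out$capacitance_pf <- pp$capacitance * 1e12
  }
  out$n_rrp_used <- n_rrp %||% NA_real_
  out$qc <- qc
  structure(out, class = "neuron_summary")
}

#' @export
print.neuron_summary <- function(x, ...) {
  cat("<neuron_summary>\n")
  flags <- x$qc
  x$qc <- NULL
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v) || all(is.na(v))) next
    cat(sprintf("  %s: %s\n", nm,
                paste(signif(as.numeric(v), 4), collapse = ", ")))
  }
  if (length(flags))
    cat("  qc:", paste(names(flags), unlist(flags), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Group-level summary of per-neuron metrics
#'
#' Plain per-group mean, SEM and n for each numeric metric.  Hierarchical
#' group statistics (e.g. estimating equations over cultures) are left to
#' dedicated statistics software; culture ids are carried through for that
#' purpose.
#'
#' @param rows List of [summarize_neuron()] results (or plain named lists).
#' @return A data.frame with columns `group`, `metric`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(rows) {
  stopifnot(length(rows) >= 1L)
  recs <- lapply(rows, function(r) {
    r <- unclass(r); r$qc <- NULL
    num <- r[vapply(r, function(v)
      is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
    data.frame(group = as.character(r$group %||% NA),
               metric = names(num), value = unlist(num),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  long <- do.call(rbind, recs)
  long <- long[long$metric != "neuron_id", , drop = FALSE]
  agg <- do.call(rbind, lapply(split(long, list(long$group, long$metric),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], metric = d$metric[1], n = nrow(d),
               mean = mean(d$value),
               sem = if (nrow(d) > 1) stats::sd(d$value) / sqrt(nrow(d))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$metric, agg$group), , drop = FALSE]
}
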