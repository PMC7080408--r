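#' Write a recording bundle to disk
#'
#' The on-disk format is deliberately plain: a JSON descriptor
#' (`descriptor.json`) holding the sampling rate, metadata and per-sweep
#' protocols, plus one single-column text file of samples (SI units) per
#' sweep.  [read_bundle()] restores the bundle; metadata and protocols round
#' trip exactly and samples round trip to double precision.
#'
#' @param bundle A [recording_bundle()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  sweeps <- lapply(names(bundle$traces), function(id) {
    tr <- bundle$traces[[id]]
    p <- bundle$protocols[[id]]
    file <- paste0(id, ".txt")
    writeLines(sprintf("%.17g", tr$samples), file.path(path, file))
    list(id = id, file = file, role = tr$role, t0 = tr$t0,
         protocol = list(
           ap_times = p$ap_times, ap_duration = p$ap_duration,
           sucrose_window = p$sucrose_window, train = p$train,
           ca_ext = p$ca_ext, ttx_present = p$ttx_present,
           negative_control = p$negative_control, reference = p$reference))
  })
  desc <- list(format = "synaptiq-bundle", version = 1L,
               sampling_rate_hz = 1 / bundle$traces[[1]]$dt,
               units = list(vc_current = "A", cc_voltage = "V", time = "s"),
               metadata = bundle$metadata, sweeps = sweeps)
  jsonlite::write_json(desc, file.path(path, "descriptor.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' @param path Directory previously written by [write_bundle()] (or any
#'   directory with a conforming `descriptor.json` and per-sweep sample
#'   files).
#' @return A [recording_bundle()].
#' @export
read_bundle <- function(path) {
  descf <- file.path(path, "descriptor.json")
  if (!file.exists(descf))
    stop("no descriptor.json found in ", path)
  desc <- jsonlite::read_json(descf, simplifyVector = FALSE)
  if (is.null(desc$sampling_rate_hz))
    stop("descriptor is missing required key 'sampling_rate_hz'")
  dt <- 1 / as.numeric(desc$sampling_rate_hz)
  traces <- list(); protocols <- list()
  for (sw in desc$sweeps) {
    id <- sw$id
    if (is.null(id)) stop("sweep entry without an id in descriptor")
    f <- file.path(path, sw$file)
    if (!file.exists(f)) stop(sprintf("sweep '%s': data file %s missing", id, sw$file))
    samples <- scan(f, what = numeric(), quiet = TRUE)
    p <- sw$protocol
    ap_times <- as.numeric(unlist(p$ap_times))
    if (length(ap_times) > 1L && any(diff(ap_times) <= 0))
      stop(sprintf("sweep '%s': ap_times are not strictly increasing", id))
    prot <- stim_protocol(
      ap_times = ap_times,
      ap_duration = as.numeric(p$ap_duration %||% 2e-3),
      sucrose_window = if (!is.null(p$sucrose_window))
        as.numeric(unlist(p$sucrose_window)),
      train = if (!is.null(p$train))
        list(frequency = as.numeric(p$train$frequency),
             count = as.integer(p$train$count)),
      ca_ext = as.numeric(p$ca_ext %||% 2),
      ttx_present = isTRUE(p$ttx_present),
      negative_control = isTRUE(p$negative_control),
      reference = isTRUE(p$reference))
    t0 <- as.numeric(sw$t0 %||% 0)
    if (!is.null(prot$sucrose_window)) {
      span <- c(t0, t0 + length(samples) * dt)
      if (prot$sucrose_window[1] < span[1] || prot$sucrose_window[2] > span[2])
        stop(sprintf("sweep '%s': sucrose window outside the trace span", id))
    }
    traces[[id]] <- trace(samples, dt = dt,
                          role = sw$role %||% "vc_current", t0 = t0)
    protocols[[id]] <- prot
  }
  meta <- lapply(desc$metadata, function(v) if (is.list(v)) unlist(v) else v)
  recording_bundle(traces, protocols, metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
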