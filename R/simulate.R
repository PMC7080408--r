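#' Ground-truth parameters of the simulated quantal synapse
#'
#' Collects every parameter of the stochastic synapse model used by
#' [simulate_minis()], [simulate_evoked()], [simulate_sucrose()] and
#' [simulate_ca_series()].  The model is a single homogeneous readily
#' releasable pool (RRP) of `n_rrp` vesicles obeying first-order kinetics
#' `r = k * A`: each vesicle fuses spontaneously at rate `k_spont`,
#' asynchronously after an AP at rate `k_async * exp(-t/tau_async)`, and
#' under hypertonic sucrose at rate `k_sucrose`; an AP releases each
#' available vesicle with probability `p_vr` scaled by the Hill factor of
#' the external calcium concentration; the pool refills towards `n_rrp` at
#' rate `k_replenish * (n_rrp - N)`.  Every fusion adds one quantal kernel
#' (see [quantal_kernel()]) to the current trace.
#'
#' @param n_rrp Number of vesicles in the RRP (the `A` of `r = k A`).
#' @param q_amp Quantal peak amplitude (A), default 20 pA.
#' @param tau_rise,tau_decay Kernel time constants (s), defaults 0.5 and 3 ms.
#' @param p_vr Per-AP, per-vesicle fusion probability at `ca_ref`.
#' @param k_spont Spontaneous fusion rate constant per vesicle (1/s).
#' @param k_async Asynchronous fusion rate constant per vesicle immediately
#'   after an AP (1/s); decays with `tau_async`.
#' @param tau_async Decay time constant of the asynchronous rate (s).
#' @param k_replenish First-order pool refill rate constant (1/s).
#' @param k_sucrose Fusion rate constant per vesicle under sucrose (1/s).
#' @param hill_ec50,hill_n Hill parameters of the calcium dependence of
#'   evoked release (mM, dimensionless).
#' @param ca_ref Calcium concentration (mM) at which `p_vr` is specified.
#' @param noise_sd Gaussian recording noise SD (A).
#' @param sync_latency,sync_jitter Mean and SD (s) of the Gaussian synaptic
#'   latency of synchronous fusions after the end of the depolarization
#'   command.
#' @param sucrose_ramp Duration (s) of the linear onset ramp of the sucrose
#'   fusion rate, mimicking solution exchange.
#' @param seed Optional default seed used by the simulators.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(n_rrp = 5000, q_amp = pA(20), tau_rise = 0.5e-3,
                           tau_decay = 3e-3, p_vr = 0.1, k_spont = 1e-3,
                           k_async = 0.1, tau_async = 0.1, k_replenish = 0.1,
                           k_sucrose = 1.5, hill_ec50 = 0.94, hill_n = 1.92,
                           ca_ref = 2, noise_sd = pA(4),
                           sync_latency = 1e-3, sync_jitter = 0.7e-3,
                           sucrose_ramp = 0.2, seed = NULL) {
  p <- list(n_rrp = n_rrp, q_amp = q_amp, tau_rise = tau_rise,
            tau_decay = tau_decay, p_vr = p_vr, k_spont = k_spont,
            k_async = k_async, tau_async = tau_async,
            k_replenish = k_replenish, k_sucrose = k_sucrose,
            hill_ec50 = hill_ec50, hill_n = hill_n, ca_ref = ca_ref,
            noise_sd = noise_sd, sync_latency = sync_latency,
            sync_jitter = sync_jitter, sucrose_ramp = sucrose_ramp,
            seed = seed)
  rates <- c(p$k_spont, p$k_async, p$k_replenish, p$k_sucrose)
  if (any(rates < 0)) stop("all rate constants must be >= 0")
  if (p$p_vr < 0 || p$p_vr > 1) stop("p_vr must lie in [0, 1]")
  if (p$hill_n <= 0 || p$hill_ec50 <= 0) stop("Hill parameters must be > 0")
  if (p$n_rrp < 1) stop("n_rrp must be >= 1")
  structure(p, class = "synapse_params")
}

#' Hill factor of the calcium dependence
#'
#' `h(c) = c^n / (c^n + ec50^n)`, the saturating occupancy term used to
#' scale the vesicular release probability with external calcium.
#'
#' @param ca Calcium concentration(s), mM.
#' @param ec50 Half-maximal concentration, mM.
#' @param n Hill coefficient.
#' @return Numeric in (0, 1).
#' @export
hill_factor <- function(ca, ec50, n) ca^n / (ca^n + ec50^n)

# effective per-vesicle release probability at a given [Ca2+]ext
.p_eff <- function(params, ca) {
  p <- params$p_vr * hill_factor(ca, params$hill_ec50, params$hill_n) /
    hill_factor(params$ca_ref, params$hill_ec50, params$hill_n)
  min(max(p, 0), 1)
}

# --- event-driven pool simulation -------------------------------------------
#
# Exact Gillespie simulation with thinning for the time-varying channels
# (asynchronous decay after APs, sucrose onset ramp).  Within a segment the
# asynchronous envelope only decays and the pool only shrinks on fusion, so
# the rate evaluated at the segment entry (with the sucrose rate replaced by
# its in-window maximum) is a valid thinning bound.
.sim_pool <- function(params, duration, ap_times = numeric(), p_eff = NULL,
                      sucrose_window = NULL, ap_duration = 2e-3) {
  n_rrp <- params$n_rrp
  N <- n_rrp
  tau_a <- params$tau_async
  ramp <- params$sucrose_ramp
  cap <- 1024L
  ev_t <- numeric(cap); ev_m <- character(cap); n_ev <- 0L
  rep_t <- numeric(cap); n_rep <- 0L
  push_ev <- function(t, m) {
    k <- length(t)
    while (n_ev + k > length(ev_t)) {
      ev_t <<- c(ev_t, numeric(length(ev_t)))
      ev_m <<- c(ev_m, character(length(ev_m)))
    }
    ev_t[(n_ev + 1L):(n_ev + k)] <<- t
    ev_m[(n_ev + 1L):(n_ev + k)] <<- m
    n_ev <<- n_ev + k
  }
  push_rep <- function(t) {
    n_rep <<- n_rep + 1L
    if (n_rep > length(rep_t)) rep_t <<- c(rep_t, numeric(length(rep_t)))
    rep_t[n_rep] <<- t
  }
  suc_rate <- function(t) {
    if (is.null(sucrose_window) || t < sucrose_window[1] || t >= sucrose_window[2])
      return(0)
    frac <- if (ramp > 0) min((t - sucrose_window[1]) / ramp, 1) else 1
    params$k_sucrose * frac
  }
  in_suc <- function(t) !is.null(sucrose_window) &&
    t >= sucrose_window[1] && t < sucrose_window[2]

  bounds <- sort(unique(c(0, duration, ap_times[ap_times < duration],
                          if (!is.null(sucrose_window)) sucrose_window)))
  bounds <- bounds[bounds >= 0 & bounds <= duration]
  env <- 0          # asynchronous envelope sum(exp(-(t - t_ap)/tau_a))
  env_t <- 0
  adv_env <- function(t) { if (t > env_t) { env <<- env * exp(-(t - env_t) / tau_a)
                                            env_t <<- t } }
  for (b in seq_len(length(bounds) - 1L)) {
    t <- bounds[b]; t_end <- bounds[b + 1L]
    pending <- numeric(0)
    if (t %in% ap_times) {                 # synchronous release at this AP
      n_f <- stats::rbinom(1L, N, p_eff %||% 0)
      if (n_f > 0) {
        lat <- ap_duration + stats::rnorm(n_f, params$sync_latency,
                                          params$sync_jitter)
        lat <- pmin(pmax(lat, ap_duration + 1e-4), ap_duration + 6e-3)
        pending <- sort(t + lat)
      }
      adv_env(t); env <- env + 1           # arm the asynchronous channel
    }
    repeat {
      adv_env(t)
      k_suc_bound <- if (in_suc((t + t_end) / 2)) params$k_sucrose else 0
      lam_bar <- N * (params$k_spont + params$k_async * env + k_suc_bound) +
        params$k_replenish * (n_rrp - N)
      t_next_pend <- if (length(pending)) pending[1] else Inf
      if (lam_bar <= 0) {
        if (length(pending)) {          # no stochastic channel is active yet:
          k <- min(length(pending), N)  # deliver the scheduled fusions in bulk
          if (k > 0) {
            push_ev(pending[seq_len(k)], "synchronous")
            N <- N - k
            t <- pending[k]
          }
          pending <- numeric(0)
          next                          # the deficit may arm replenishment
        }
        t <- t_end
        break
      }
      t_cand <- t + stats::rexp(1L, lam_bar)
      if (t_next_pend <= min(t_cand, t_end)) {   # scheduled synchronous fusion
        t <- t_next_pend; pending <- pending[-1L]
        if (N > 0) { N <- N - 1L; push_ev(t, "synchronous") }
        next
      }
      if (t_cand >= t_end) { t <- t_end; break }
      t <- t_cand
      adv_env(t)
      r_sp <- N * params$k_spont
      r_as <- N * params$k_async * env
      r_su <- N * suc_rate(t)
      r_re <- params$k_replenish * (n_rrp - N)
      lam <- r_sp + r_as + r_su + r_re
      if (stats::runif(1L) * lam_bar > lam) next   # thinned
      u <- stats::runif(1L) * lam
      if (u < r_sp)                { N <- N - 1L; push_ev(t, "spontaneous") }
      else if (u < r_sp + r_as)    { N <- N - 1L; push_ev(t, "asynchronous") }
      else if (u < r_sp + r_as + r_su) { N <- N - 1L; push_ev(t, "sucrose") }
      else                         { N <- N + 1L; push_rep(t) }
    }
  }
  ord <- order(ev_t[seq_len(n_ev)])
  list(fusion_times = ev_t[seq_len(n_ev)][ord],
       fusion_mode = ev_m[seq_len(n_ev)][ord],
       replenish_times = sort(rep_t[seq_len(n_rep)]))
}

#' Ground-truth event log of a simulated sweep
#'
#' Created by the simulators; records every vesicle fusion (time and mode)
#' and every replenishment event, from which the pool trajectory follows by
#' conservation: `N(t) = n_rrp - fused(t) + replenished(t)`.
#'
#' @param log A `ground_truth` object.
#' @param times Times (s) at which to evaluate the pool size.
#' @return `pool_at`: integer pool sizes at `times`.
#' @name ground_truth
NULL

.ground_truth <- function(sim, n_rrp) {
  structure(list(fusion_times = sim$fusion_times,
                 fusion_mode = sim$fusion_mode,
                 replenish_times = sim$replenish_times,
                 n_rrp = n_rrp),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @export
pool_at <- function(log, times) {
  stopifnot(inherits(log, "ground_truth"))
  fused <- findInterval(times, log$fusion_times)
  repl <- findInterval(times, log$replenish_times)
  log$n_rrp - fused + repl
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d fusions (%s), %d replenishments, n_rrp = %d\n",
              length(x$fusion_times),
              paste(names(table(x$fusion_mode)), table(x$fusion_mode),
                    sep = ":", collapse = ", "),
              length(x$replenish_times), x$n_rrp))
  invisible(x)
}

# --- trace rendering --------------------------------------------------------

.render_trace <- function(fusion_times, params, duration, dt = 1e-4,
                          blank_windows = NULL, acq_cutoff = 3000) {
  n <- ceiling(duration / dt)
  y <- numeric(n)
  if (length(fusion_times)) {
    ker <- quantal_kernel(params$q_amp, params$tau_rise, params$tau_decay, dt)
    idx <- pmax(1L, round(fusion_times / dt) + 1L)
    idx <- idx[idx <= n]
    counts <- tabulate(idx, nbins = n)
    # superpose all kernels at once: convolve the per-sample fusion counts
    # with the quantal kernel
    nfft <- stats::nextn(n + length(ker), 2)
    conv <- Re(stats::fft(stats::fft(c(counts, numeric(nfft - n))) *
                          stats::fft(c(ker, numeric(nfft - length(ker)))),
                          inverse = TRUE)) / nfft
    y <- conv[seq_len(n)]
  }
  if (params$noise_sd > 0) y <- y + stats::rnorm(n, 0, params$noise_sd)
  tr <- trace(y, dt = dt)
  if (!is.null(acq_cutoff) && acq_cutoff < 0.5 / dt)
    tr <- lowpass_filter(tr, acq_cutoff)
  if (!is.null(blank_windows)) {
    for (w in blank_windows) tr <- .blank_artifact(tr, w)
  }
  tr
}

# replace the artifact window with a linear interpolation of its endpoints
.blank_artifact <- function(tr, window) {
  i0 <- max(1L, floor((window[1] - tr$t0) / tr$dt) + 1L)
  i1 <- min(length(tr$samples), ceiling((window[2] - tr$t0) / tr$dt) + 1L)
  if (i1 > i0) {
    tr$samples[i0:i1] <- seq(tr$samples[i0], tr$samples[i1],
                             length.out = i1 - i0 + 1L)
  }
  tr
}

.set_seed <- function(seed, params) {
  s <- seed %||% params$seed
  if (!is.null(s)) set.seed(s)
  invisible(s)
}

# --- public simulators ------------------------------------------------------

#' Simulate a miniature-event (TTX) sweep
#'
#' Spontaneous fusions are drawn as a Poisson process with instantaneous
#' rate `k_spont * N(t)`; each fusion adds one quantal kernel; Gaussian
#' noise is added and the trace is low-pass filtered at the acquisition
#' bandwidth.
#'
#' @param params A [synapse_params()].
#' @param duration Sweep duration (s).
#' @param seed Integer seed (defaults to `params$seed`).
#' @param negative_control Mark the sweep as a receptor-blocked (KYN)
#'   control; the synaptic signal is suppressed and only noise remains.
#' @return `list(bundle = recording_bundle, log = ground_truth)`.
#' @export
simulate_minis <- function(params, duration = 90, seed = NULL,
                           negative_control = FALSE) {
  .set_seed(seed, params)
  sim <- .sim_pool(params, duration)
  ft <- if (negative_control) numeric() else sim$fusion_times
  tr <- .render_trace(ft, params, duration)
  prot <- stim_protocol(ttx_present = TRUE, negative_control = negative_control)
  bundle <- recording_bundle(list(s1 = tr), list(s1 = prot))
  list(bundle = bundle, log = .ground_truth(sim, params$n_rrp))
}

#' Simulate AP-evoked sweeps
#'
#' At each AP command, every available vesicle fuses with probability
#' `p_vr` scaled by the Hill factor at the protocol's calcium
#' concentration; fused vesicles leave the pool, which refills at rate
#' `k_replenish * (n_rrp - N)`; asynchronous fusions follow each AP at rate
#' `k_async * N * exp(-t/tau_async)`.  The 2 ms depolarization window is
#' blanked in the output trace (linear interpolation), as an analyst would
#' treat the stimulus artifact.
#'
#' @param params A [synapse_params()].
#' @param protocol A [stim_protocol()] with at least one AP time.
#' @param duration Sweep duration (s); default extends 0.6 s past the last AP.
#' @param seed Integer seed.
#' @return `list(bundle, log)` as in [simulate_minis()].
#' @export
simulate_evoked <- function(params, protocol, duration = NULL, seed = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (!length(protocol$ap_times)) stop("protocol has no ap_times")
  .set_seed(seed, params)
  duration <- duration %||% (max(protocol$ap_times) + 0.6)
  p_eff <- .p_eff(params, protocol$ca_ext)
  sim <- .sim_pool(params, duration, ap_times = protocol$ap_times,
                   p_eff = p_eff, ap_duration = protocol$ap_duration)
  blanks <- lapply(protocol$ap_times,
                   function(t) c(t, t + protocol$ap_duration))
  tr <- .render_trace(sim$fusion_times, params, duration, blank_windows = blanks)
  bundle <- recording_bundle(list(s1 = tr), list(s1 = protocol))
  list(bundle = bundle, log = .ground_truth(sim, params$n_rrp))
}

#' Simulate a hypertonic-sucrose application
#'
#' During the application window every pooled vesicle fuses at rate
#' `k_sucrose`, reached through a linear onset ramp of `params$sucrose_ramp`
#' seconds that mimics solution exchange; the pool refills at
#' `k_replenish * (n_rrp - N)` throughout; outside the window only
#' spontaneous fusion occurs.
#'
#' @param params A [synapse_params()].
#' @param duration Sweep duration (s).
#' @param window `c(start, end)` of the sucrose application (s); default a
#'   5 s application starting at 2 s.
#' @param seed Integer seed.
#' @return `list(bundle, log)` as in [simulate_minis()].
#' @export
simulate_sucrose <- function(params, duration = 10, window = c(2, 7),
                             seed = NULL) {
  if (duration < window[2]) stop("duration must cover the sucrose window")
  .set_seed(seed, params)
  sim <- .sim_pool(params, duration, sucrose_window = window)
  tr <- .render_trace(sim$fusion_times, params, duration)
  prot <- stim_protocol(sucrose_window = window, ttx_present = TRUE)
  bundle <- recording_bundle(list(s1 = tr), list(s1 = prot))
  list(bundle = bundle, log = .ground_truth(sim, params$n_rrp))
}

#' Simulate a calcium dose-response series
#'
#' One evoked sweep set per external calcium concentration, with the
#' per-vesicle release probability scaled by the Hill factor, plus
#' interleaved standard-solution (reference) sweeps at `params$ca_ref`
#' before each concentration block for the stability check of
#' [build_ca_series()].
#'
#' @param params A [synapse_params()].
#' @param ca_list Calcium concentrations (mM).
#' @param sweeps_per_ca Sweeps per concentration.
#' @param ap_time AP command time within each sweep (s).
#' @param seed Integer seed.
#' @return A [recording_bundle()]; sweep ids encode concentration and the
#'   reference sweeps carry `reference = TRUE`.
#' @export
simulate_ca_series <- function(params, ca_list = c(0.5, 2, 4, 10),
                               sweeps_per_ca = 1, ap_time = 0.1, seed = NULL) {
  if (!length(ca_list)) stop("ca_list must be non-empty")
  .set_seed(seed, params)
  params$seed <- NULL   # inner sweeps continue the stream set above
  traces <- list(); protocols <- list()
  add_sweep <- function(id, ca, reference) {
    prot <- stim_protocol(ap_times = ap_time, ca_ext = ca,
                          reference = reference)
    sim <- simulate_evoked(params, prot, duration = ap_time + 0.4, seed = NULL)
    traces[[id]] <<- sim$bundle$traces$s1
    protocols[[id]] <<- prot
  }
  k <- 0L
  for (ca in ca_list) {
    k <- k + 1L
    add_sweep(sprintf("ref%02d", k), params$ca_ref, reference = TRUE)
    for (s in seq_len(sweeps_per_ca))
      add_sweep(sprintf("ca%g_%02d", ca, s), ca, reference = FALSE)
  }
  recording_bundle(traces, protocols,
                   metadata = list(protocol = "ca_series"))
}
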