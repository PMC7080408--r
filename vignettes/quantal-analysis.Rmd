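---
title: "Quantal analysis of synaptic vesicle release: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of synaptic vesicle release: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptiq)
```

This vignette is the package's own account of the science it implements:
the release model behind the simulator, the estimators and their
assumptions, the numerical choices, and the known limitations. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The release model

A glutamatergic neuron in autaptic culture is reduced to a single
homogeneous readily releasable pool (RRP) of `n_rrp` vesicles. Every mode of
release obeys the first-order law *r = k·A*: the observed vesicle release
rate *r* (SV/s) is a rate constant *k* times the number *A* of vesicles
currently in the pool. The modes differ only in *k*:

* **spontaneous** fusion at `k_spont` per vesicle (≈10⁻³ s⁻¹), present
  throughout a sweep;
* **synchronous** evoked release: at each action potential (AP) every
  available vesicle fuses with probability `p_vr`, scaled by the Hill
  factor `h(c) = cⁿ/(cⁿ + EC₅₀ⁿ)` of the external calcium concentration,
  normalized to the reference solution (`p_eff = p_vr · h(c)/h(c_ref)`,
  clipped to [0, 1]);
* **asynchronous** release after each AP at
  `k_async · exp(-t/tau_async)` per vesicle;
* **sucrose-driven**, calcium-independent fusion at `k_sucrose` per vesicle
  during a hypertonic application.

Fused vesicles leave the pool; the pool refills toward `n_rrp` at
`k_replenish · (n_rrp - N)`. Each fusion adds one biexponential quantal
current `q·(e^{-t/τ_d} - e^{-t/τ_r})`, normalized so its peak is the quantal
amplitude `q_amp`; its charge has the closed form
`q_amp (τ_d - τ_r) / peak_factor` (`quantal_charge()`). Gaussian recording
noise is added and the trace is low-pass filtered at the acquisition
bandwidth (3 kHz on the 10 kHz grid).

### Simulation scheme

The pool is simulated exactly by a Gillespie algorithm with thinning for
the time-varying channels. Between stimuli the asynchronous envelope only
decays and fusion only shrinks the pool, so the total rate evaluated at the
segment entry (with the sucrose rate replaced by its in-window maximum) is
a valid thinning bound. Synchronous fusions are drawn binomially at the AP
and delivered at latencies `ap_duration + N(sync_latency, sync_jitter)`
(defaults 1 ± 0.7 ms after the 2 ms depolarization command, truncated to
[0.1, 6] ms) — a compound-EPSC dispersion typical of cultured synapses.
Every fusion and replenishment is logged; the pool trajectory follows by
conservation, `N(t) = n_rrp - fused(t) + replenished(t)`, which the test
suite asserts on every protocol. The trace is rendered by convolving the
per-sample fusion counts with the quantal kernel (FFT), so
trace = Σ kernels + noise holds by construction.

### Default study conditions

The defaults of `synapse_params()` are the conditions the analyses are
validated under: `n_rrp = 5000` vesicles, `q_amp = 20 pA`, kernel
`τ_r = 0.5 ms`, `τ_d = 3 ms` (the same constants as the detection
template), `p_vr = 0.1`, `k_spont = 10⁻³ s⁻¹`, `k_async = 0.1 s⁻¹` with
`tau_async = 0.1 s`, `k_replenish = 0.1 s⁻¹`, `k_sucrose = 1.5 s⁻¹`, Hill
`EC₅₀ = 0.94 mM`, `n = 1.92`, reference calcium 2 mM, noise SD 4 pA.
These sit where cultured glutamatergic neurons typically sit (mini rates of
a few Hz, RRPs of a few hundred pC, sub-unity release probabilities). The
sucrose rate is reached through a 200 ms linear onset ramp standing in for
solution exchange; the ramp is a simulator parameter, not a claim about any
particular perfusion system.

## Miniature-event detection

`detect_events()` slides a biexponential template (0.5 ms rise, 3 ms decay)
along the 1 kHz-filtered trace and fits `scale·template + offset` by least
squares at every offset — the scaled-template matched filter of the
Clements–Bekkers family. Two conditions make a detection:

1. the fitted template peak exceeds `threshold_sd` (default 3) times the
   baseline SD of the filtered trace, estimated by the median absolute
   deviation so the events themselves cannot inflate it;
2. the scale/standard-error criterion of the fit is significant at the same
   multiple.

The trace and the template are filtered identically, which keeps the
amplitude estimate unbiased. Detections are restricted to local maxima of
the fitted scale within a refractory window of one template decay, and the
expected tail response of each accepted event — the template's least-squares
fit to its own shifted copy, precomputed once — is subtracted from later
fitted scales before re-thresholding. This linear peeling prevents a single
event's decay from being counted twice while leaving genuinely overlapping
events detectable.

With the amplitude threshold at 3×SD the false-positive rate on pure-noise
sweeps is far below the 0.5 Hz bound the tests assert (a threshold of 3 on
the *statistical criterion alone* would produce multi-Hz Gaussian-tail
crossings, which is why the amplitude reading is used). Residual false
positives in real data are handled downstream by the negative-control
correction: `correct_false_positives()` discards a neuron when the
receptor-blocked control frequency exceeds 0.25 of the raw frequency, and
otherwise subtracts control from raw frequency and corrects the mean
amplitude by rate-weighted mean subtraction
`(f_r·Ā_r − f_c·Ā_c)/(f_r − f_c)`, the reading of "subtracting the
amplitude of false positives" that conserves total amplitude mass.

`compute_srr()` divides the (corrected) mini frequency by the RRP size;
`dwell_time()` reports its reciprocal rounded to whole seconds.

## Evoked analysis

`measure_eepsc()` baselines to the 5 ms before the stimulus, takes the peak
inward deflection after the blanked 2 ms artifact, and fits a single
exponential to the fast decay. The exponential is seeded by a log-linear
regression restricted to the early decay (above 10% of the peak) so a slow
asynchronous tail cannot corrupt the initial time constant, then refined by
`nls` over five seeded time constants. The synchronous ("fast") charge is
the measured rising-phase charge up to the peak **plus** the analytic decay
area `amp·τ`; the rising term matters because latency jitter spreads the
compound EPSC onset over a few ms, and `peak·τ` alone would misassign that
charge to the asynchronous residual. The asynchronous charge is the total
minus the fast component, clipped at zero, and `async_rate_single()`
converts it to a rate constant over a configurable window (default 0.5 s —
the assay needs a time base and none is canonical; with `tau_async` longer
than the window the recovered constant approximates `k_async`).

`deconvolve_release_rate()` divides the EPSC by the signed quantal charge
and deconvolves with the unit-charge mini kernel in the frequency domain
with Wiener regularization `λ = nsr·max|H|²`. When no `nsr` is given it is
estimated as the spectral noise floor (`n·σ²` from a pre-stimulus window)
over the peak signal power of the spectrum — the band where the release
transient lives; comparing noise to the *average* spectrum would
over-smooth, since most of a sweep is baseline. The running integral of the
rate waveform counts vesicles; `peak_release_rate()` takes its maximum
slope over a sliding 1 ms bin and divides by the RRP.

`compute_ppr()` measures the paired-pulse ratio after subtracting the
fitted exponential tail of the first response under the second. In the
depletion model the expectation is `1 − p·e^{−k_rep·Δ}`, which the tests
verify over a grid of `p`, `k_rep` and interval `Δ` to within three
Monte-Carlo standard errors.

## Train and sucrose estimators

`analyze_train()` integrates each EPSC of a 50 Hz, 80-stimulus train over
its inter-stimulus interval against the pre-train baseline (so asynchronous
build-up is included in the cumulative charge), fits a line to the last 20
cumulative points, and reports intercept (RRP_train), first-charge /
intercept (train release probability) and slope·frequency / intercept
(replenishment rate). For pure depletion, `Q_i = q·N₀·p(1−p)^{i−1}`, the
intercept converges to `N₀·q`; the tests assert this on noiseless
closed-form trains. `async_rate_train()` applies the stated depletion
correction `A* = n_rrp·Q_last/Q_first`; because per-AP asynchronous
envelopes summate during a train, the measured constant is the actual
per-vesicle fusion rate in the last interval, and the tests validate it
against the event-log oracle rather than against the kernel parameter.
`post_train_srr()` re-runs the detector on the 10 s window beginning 100 ms
after the last stimulus.

`rrp_from_sucrose()` estimates the steady state over the final 20% of the
5 s application (unspecified in the field's descriptions; the final fifth
is comfortably past the transient at the default kinetics) and integrates
the response above it. This is unbiased when replenishment is silent; with
replenishment active it understates the pool by roughly
`k_suc/(k_suc + k_rep)·(1 − N*/N₀)` — the method's intrinsic bias, visible
in the worked example. `sucrose_peak_rate()` normalizes the cumulative
released fraction F(t) by the RRP, takes the maximal slope over a 50 ms bin
(raw-sample slopes are noise-dominated), and divides by the fraction of the
pool remaining at that moment — the direct reading of *r = k·A*. Without
that division the onset ramp depletes ~10–15% of the pool before the rate
peaks and `k_sucrose` is correspondingly understated.

## Calcium dose–response

`build_ca_series()` averages peak amplitudes per concentration, applies the
stability rule (exclude the neuron if any interleaved standard-solution
amplitude shifts more than 20% from the first — the first is the comparator
since the rule's wording names none), and normalizes to 10 mM.
`fit_hill()` fits `amax·cⁿ/(cⁿ + EC₅₀ⁿ)` by Levenberg–Marquardt with
`amax` free, because 10 mM need not be fully saturating. A pooled fit of
the normalized means is the default mode; per-neuron fits followed by
cohort averaging are what the acceptance script uses, matching how
dose–response cohorts are summarized. With `amax` free and four
concentrations the fitted EC₅₀ carries a small positive finite-sample bias
(~3% at 5% noise), which is why recovery is asserted within two standard
errors of the Monte-Carlo mean rather than one.

## Membrane metrics

`passive_properties()` takes R_in from the steady-state deflection of a
−20 pA, 0.5 s step, τ from an exponential fit of the charging transient,
and returns C = τ/R_in — an identity by construction, asserted as such.
`ap_metrics()` defines threshold as the voltage at the maximum second time
derivative of the low-pass-smoothed rising phase (an inflection criterion);
a dV/dt-crossing mode (default 10 mV/ms) is provided since published
numeric criteria vary. Amplitude is peak minus threshold. No liquid
junction correction is applied.

## Numerical choices, problem sizes, degenerate inputs

* Zero-phase 4th-order Butterworth filtering throughout (`signal::filtfilt`)
  so latencies are not shifted; DC gain 1.
* SNR conventions: detection tests use peak SNR = quantal amplitude / raw
  noise SD; the deconvolution round trip uses trace-level SNR = signal RMS /
  noise SD over the response window.
* Charge integration is trapezoidal on the baseline-subtracted trace;
  inward (negative) current reports positive charge.
* Degenerate inputs are flagged, never silently defaulted: zero raw mini
  frequency, non-positive RRP intercepts or transient charges, fit
  non-convergence, sub-noise-floor first responses in paired pulses.
* Test problem sizes — pools of 10³–10⁴ vesicles (10⁶ for noise-free
  Hill-ratio identities), sweeps of 10–90 s, cohorts of 10–20 seeds — are
  chosen so Monte-Carlo tolerances (3 SE, or the stated recovery bands)
  are meaningful while a full run stays inexpensive.

## What the simulator does and does not emulate

It emulates the protocol battery end to end: Poisson minis on a depleting
pool, binomial AP release with calcium scaling, summating asynchronous
kernels, first-order replenishment, ramped sucrose fusion, interleaved
reference sweeps, recording noise and artifact blanking. It does **not**
emulate quantal size variability, receptor saturation or desensitization,
series-resistance distortion, multivesicular release correlations, spatial
heterogeneity across boutons, or molecularly distinct vesicle pools.
Passing recovery tests therefore demonstrate that the estimators are
correct for the stated model at realistic signal-to-noise — not that real
recordings satisfy the model. In particular, the assumption that
spontaneous, asynchronous and evoked release all draw on the sucrose-defined
pool is a modeling choice carried over from the assay's logic, and the
depletion correction `A* = n_rrp·Q_last/Q_first` is known to understate
depletion when release probability grows during a train; the package
implements the stated correction and exposes the oracle comparison in its
tests rather than "improving" it.

## Known limitations

* The sucrose RRP and the quantities derived from it inherit the
  replenishment bias described above; estimates of `k_replenish` from the
  sucrose steady state and from trains are both biased and are asserted
  against each other for consistency (within 35%), not exactness.
* Mini detection assumes a stationary baseline; slow drift should be
  removed (or the sweep windowed) before detection.
* The Hill fit needs at least four concentrations spanning the EC₅₀; with
  exactly four and a free `amax` the parameter errors are strongly
  correlated.
* No reader for proprietary acquisition formats is included; the bundle
  format (JSON descriptor + one numeric column file per sweep) is the
  interchange surface.
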