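---
title: "Quantifying sensory-flicker responses in intracranial LFP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sensory-flicker responses in intracranial LFP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Rhythmic sensory stimulation ("flicker") — light and/or sound pulsed at a
fixed frequency with 50% duty cycle — evokes a periodic neural response,
the steady-state evoked potential (steady-state EP), measurable in
intracranial local field potential (LFP) recordings from depth
electrodes. `flickerlfp` implements a complete analysis chain for such
experiments:

1. **Preprocessing** — Laplacian/bipolar re-referencing along depth
   electrodes, segmentation into padded trial windows, zero-phase
   band-pass filtering, and trial-count balancing across conditions.
2. **Steady-state quantification** — per-trial multitaper power spectra;
   fold-change in power at the stimulation frequency against baseline
   with a trial-permutation test; inter-trial phase-locking value (PLV)
   with a Rayleigh test; a two-cycle evoked-waveform average.
3. **Single-pulse analysis** — evoked potentials to isolated 12.5 ms
   pulses, significance against an occluded control via a
   root-mean-square permutation statistic, amplitude normalization, and
   the linear-superposition counterfactual simulation.
4. **Resonance / entrainment** — spectral parameterization of baseline
   spectra into a 1/f aperiodic component plus Gaussian oscillation
   peaks; per-contact frequency-preference profiles across a
   26-frequency paradigm; matching of preferred stimulation frequencies
   to endogenous oscillations.
5. **Spiking** — unit classification from sorting-quality features,
   cycle-pair peristimulus histograms, vector strength and Rayleigh
   statistics.
6. **Interictal discharges (IEDs)** — polyspike merging, wide-event
   rejection, the proportion-during-stimulation statistic, and the
   one-sided group test against 0.5.
7. **Anatomical assignment** — distance-weighted label voting in a 5 mm
   search sphere around each contact.

A synthetic-session generator with fully known ground truth
(`ground_truth()`, `make_lfp_session()`, `make_spikes()`, `make_ieds()`)
drives all validation; no human recordings ship with the package.

# The measurement model

## Referencing

Depth-electrode contacts record a mixture of local currents and
volume-conducted activity. The Laplacian montage subtracts from each
contact the mean of its two nearest neighbors on the same probe,
`x_i - (x_{i-1} + x_{i+1})/2`, which cancels any signal common to the
probe (it is exactly zero for a probe-wide common signal, and linear).
Probe-end contacts fall back to bipolar referencing. When a neighbor is
excluded, the nearest usable contact on the same side substitutes; a
contact with no usable neighbor at all cannot be referenced and is
excluded — the choice for this degenerate case (including single-contact
probes) is exclusion with a warning, since an unreferenced channel would
silently carry common-mode noise into group statistics.

## Steady-state evoked potential

Each 10 s stimulation trial is segmented with 1 s pads (12 s working
segments) so that filter edge artifacts fall outside the analysis
window. Band-pass filtering (2–300 Hz) is zero-phase Butterworth,
order 4 per edge. Two realization details matter:

* The band-pass is a cascade of an order-4 high-pass and an order-4
  low-pass, each implemented as second-order sections (biquads) obtained
  from the analog Butterworth pole pairs. A direct polynomial transfer
  function is numerically unreliable at normalized cutoffs as extreme as
  2 Hz at kilohertz rates (and unusable at the 0.1 Hz edge used for
  pulse EPs); biquad cascades are well conditioned at all cutoffs used
  here.
* Zero phase is obtained by forward–backward application with
  odd-reflection end padding and steady-state initial conditions, so a
  constant input produces no start-up transient. Phase preservation is
  required because evoked waveforms are averaged time-locked to pulse
  onsets.

Power spectral densities use DPSS (Slepian) multitapers with
time–bandwidth product 3 and 5 tapers, per trial, reported on a
2–100 Hz grid. A 10 s window gives a 0.1 Hz native grid, which contains
every stimulation frequency of the paradigms exactly, so "power at the
stimulation frequency" is a nearest-bin lookup with negligible bin
error and no interpolation. The tapers come from the tridiagonal
eigenvalue formulation; windows longer than 1024 samples use
spline-interpolated tapers re-orthonormalized by QR — the taper shapes
are smooth functions of `t/N` at fixed time–bandwidth product, and the
unit tests verify agreement with an independent reference
implementation at both exact and interpolated lengths.

The amplitude measure is the **fold-change in power**
`mu_stim / mu_bl - 1`, where `mu_stim` is power at the stimulation
frequency averaged over the trials of a condition and `mu_bl` the same
over an equal number of baseline trials (hence the trial balancing).
Significance uses a one-sided random permutation test of trial labels
on `mu_stim - mu_bl` (10,000 iterations by default), with add-one
smoothing `p = (1 + #{perm >= obs})/(n_perm + 1)` so reported p-values
are never exactly zero. No multiple-comparison correction is applied
across contacts by default, matching per-contact reporting at p < 0.05;
users can apply `p.adjust` on the result tables where a corrected
population claim is needed.

## Phase locking

The stimulus is approximated by a sinusoid at the stimulation frequency
with phase zero at trial onset. Each trial is cut into non-overlapping
windows of half the sampling rate (0.5 s); in each window the
LFP–stimulus phase difference at the stimulation frequency is the
cross-spectrum angle at the nearest FFT bin. The PLV is the modulus of
the mean unit phasor. The source description averages "across trials
and time" before taking the modulus without fixing the nesting; the
default here pools all (trial, window) phasors, with
`average = "within_trial"` available to average within trial first.
Pooling uses every phase estimate symmetrically and makes the PLV
independent of how windows are grouped into trials; for stationary
locking the two options agree. Rayleigh's test
(`Z = n R^2`, `p = exp(-Z)(1 + (2Z - Z^2)/(4n))`) on the trial-mean
angles assesses non-uniformity.

## Single pulses and the superposition counterfactual

Pulse responses are extracted after a 0.1 Hz order-4 zero-phase
high-pass, in windows of −0.25 to +1.25 s around pulse onset,
baseline-corrected by the 0.25 s pre-onset mean. Significance against
the occluded control uses the difference of the RMS of the two
trial-averaged traces over 0–1 s, permuted over trial labels (500
iterations). Amplitude is the absolute maximum of the average trace
0–1 s post onset; for cross-subject comparison, amplitudes are min-max
mapped within subject × modality groups onto [0.001, 1] and log10
transformed (range [−3, 0]).

The **linear-superposition hypothesis** — that the steady-state EP is
nothing but overlapping single-pulse EPs — is evaluated by
construction: 15 simulated 10 s trials are built by drawing one recorded
single-pulse trial (with replacement; the source leaves replacement
unstated, and with-replacement draws keep the 400 slot draws
independent) at every 25 ms grid point starting at trial onset, summing
the 1 s post-onset traces, truncating tails at the trial edge, and
quantifying the result exactly like recorded flicker trials against the
same baseline. Because the drawn traces carry their own background
noise and 25 ms is one full period at 40 Hz (so repeated draws of the
same trace add coherently at the 40 Hz bin), the simulation carries a
noise floor at the stimulation frequency that a recorded trial does
not; for weakly responsive contacts this inflates the simulated
fold-change. The validation suite therefore evaluates the
measured-versus-simulated comparison on strongly responsive synthetic
contacts (pulse-kernel amplitudes of 40–120 µV against ~5 µV background,
i.e. the regime of contacts with clearly significant flicker
modulation, which is also the population the response-class comparison
conditions on).

## Resonance and entrainment

Baseline spectra are decomposed into a 1/f aperiodic component (offset
and exponent, fit in log-log space with a robust refit that masks
peak-dominated points) plus up to 5 Gaussian peaks with widths
constrained to 2–10 Hz and minimum height 0.6 (log10 power over the
aperiodic fit), over 2–100 Hz; after iterative extraction the peaks are
jointly refit by bounded Levenberg–Marquardt least squares. Each peak
reports its fold-change in linear power of the modeled spectrum at the
peak center relative to the aperiodic fit. "Has a clear endogenous
oscillation" is operationalized as at least one detected peak under
these settings — the only stated detection criterion.

For the 26-frequency paradigm (5.5–80 Hz in ~3 Hz steps, omitting
60 Hz), `frequency_profile()` runs the steady-state quantification per
frequency and tabulates per contact the number of significant
frequencies and the top frequency (argmax fold-change among significant
frequencies; ties are broken toward the lower frequency and logged —
the source is silent on ties, and the lower frequency is the
conservative choice against spuriously "high" preferences). Both a
power-based and a PLV-based top frequency are reported; fold-change is
the default for entrainment matching. A contact is eligible for the
entrainment comparison if it is significant at more than 6 of the 26
frequencies and has at least one endogenous peak; it "matches" if its
top frequency lies within 5 Hz of the nearest peak center.

## Spiking

Units are classified as single unit / multi-unit / artifact from a
decision table of sorting-quality features (waveform appearance, firing
rate, fraction of inter-event intervals under 3 ms, density-peak
narrowing, post-peak local peaks, amplitude-distribution modality). The
visual-inspection criteria enter as precomputed features: the
classifier codifies the decision rules, not the human judgments.
Cycle-pair PSTHs use the same two-cycle windows (one cycle overlap) as
the evoked average, with 20 bins per cycle — a bin count the source
does not state; 20 per cycle resolves 1.25 ms of phase at 40 Hz without
starving counts at ordinary firing rates. A unit is excluded only if
more than 20% of PSTH bins are empty in *every* condition. Phase
locking of spikes uses vector strength over stimulus phase and the
Rayleigh statistic; `vs_to_kappa()` inverts the von Mises relation
`VS = I1(kappa)/I0(kappa)` for parameter-recovery checks.

## IEDs

Detector output is post-processed by chain-merging events whose
successive times differ by at most 100 ms into one IED (polyspike),
taking the first constituent's timestamp (onset convention) and the
union of channels; chaining (rather than a fixed window from the first
spike) is used because a polyspike is defined by its internal gaps.
Merged events spanning more than 11 channels are rejected as noise.
For each stimulation trial paired with its immediately following
equal-duration baseline trial, the proportion of IEDs during
stimulation is `n_stim / (n_stim + n_base)`; empty 20 s pairs are
omitted; proportions are averaged within condition and then across
conditions — not pooled — because conditions may retain different trial
counts after omission. The session values are tested against 0.5 with
a one-sample, one-sided t-test (alternative: decrease); an all-equal
input is reported as p = 1 with a zero-variance warning rather than
NaN.

## Anatomical assignment

Each contact's label comes from a vote over atlas voxels within a 5 mm
sphere: white-matter labels are removed, each voxel contributes
`min(1, 1/r)` (the capped weight realizes "1/r, with value 1 at r = 0"
while keeping weights bounded for voxels closer than 1 mm — the source
does not specify behavior between 0 and 1 mm), and the label with the
greatest summed weight wins; ties go to the lower label id. The
"Gaussian search sphere" wording in the source conflicts with its own
enumerated 1/r steps; the explicit steps are implemented as the
default, with `weight = "gaussian"` available.

# The synthetic-data generator

`make_lfp_session()` emulates exactly the statistical structure the
analyses assume:

* **Background**: Gaussian noise spectrally shaped by FFT filtering to
  `log10 P(f) = offset − exponent·log10 f + Σ peaks`, i.e. the
  aperiodic-plus-Gaussian-peaks model the oscillation-detection stage
  fits. Endogenous oscillations are narrowband noise, so their phase
  drifts naturally.
* **Steady-state component**: a sinusoid at the stimulation frequency
  whose amplitude is calibrated analytically against the package's own
  multitaper estimator — for an on-grid sinusoid of amplitude A the
  estimated power at its bin is `A² · mean_k (Σ_t h_k)² / (2 fs)` — so
  the injected power fold-change is an exact target, not an empirical
  tuning. Per-trial phase jitter (SD in radians) makes the PLV a free
  ground-truth parameter.
* **Pulse-evoked responses**: a damped-oscillation kernel convolved with
  the stimulus pulse train (`linear_superposition`); optionally passed
  through a two-pole resonator with configurable center and Q
  (`resonant`), making response amplitude frequency-dependent; or with
  per-pulse gains `g_k = g_inf + (1 − g_inf)·exp(−k/tau)` (`adapting`),
  making the steady-state response weaker than single pulses predict.
  These three modes reproduce, by construction, the mechanistic
  alternatives the analyses are designed to distinguish.
* **Spikes**: inhomogeneous Poisson with von Mises rate modulation by
  stimulus phase; **IEDs**: piecewise-constant-rate Poisson with
  configurable channel-subset sizes and optional wide "noise" events.

Trial schedules interleave every stimulation trial with an immediately
following baseline trial of equal duration, the structure both the
fold-change balancing and the IED pairing assume.

What the generator does **not** emulate: non-Gaussian and nonstationary
background (artifacts, sleep-stage changes), harmonics of the
steady-state response, volume conduction between channels (synthetic
channels are independent and live one per probe, i.e. already
source-localized), spike waveforms (only times), and IED morphology
(only detector-style event times). Passing tests therefore demonstrate
correctness of the statistics under the model assumptions, not
robustness to every pathology of clinical recordings.

# Validation design and problem sizes

The test suite validates each stage against independent oracles:
hand-computed micro-examples (the four-contact Laplacian, the 2/8 IED
proportion, normalization endpoints, the unit-classification table);
closed forms (von Mises `I1/I0` for PLV and vector strength; analytic
Fourier coefficients for delta-kernel pulse trains); brute-force
enumerations (voxel-wise label assignment, interval clustering of IED
merges); and frozen reference values for the DPSS tapers.

Calibration and recovery checks run at sizes chosen to keep the whole
suite in the minutes range while leaving the conclusions
statistically meaningful:

* Type-I error of the two permutation tests and the IED group test:
  1000 null replicates each (permutation counts 1000 and 500; 13
  sessions of 30 trial pairs per replicate), compared against the
  binomial 95% band around 5%.
* Fold-change recovery: 12 contacts with injected fold-changes 1–4, 50
  trials per condition, median relative error under 15%.
* Peak-center recovery: 8 contacts, 5-minute baselines, median error
  under 1 Hz. Kappa recovery by VS inversion at ~10³ spikes within 10%.
* Superposition dissociation: 10 replicate populations of 6 linear
  contacts (paired comparison of measured vs simulated fold-change
  non-significant in ≥90% of runs) and 3 adapting contacts with
  `g_inf = 0.2` (measured amplitude at least 3× smaller).
* Resonance: 20 runs of a resonator contact (center 40 Hz, Q = 10 — a
  ~4 Hz bandwidth, sharp enough that the 2 Hz-away grid neighbors are
  distinguishable at 10 trials per condition) across the full
  26-frequency paradigm; the top frequency must hit 40 Hz in ≥95% of
  runs. A low-pass kernel contact in pure superposition mode must show
  a monotone-decreasing noiseless fold-change profile — the
  superposition prediction that resonant contacts violate.

`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed and writes them as JSON.

# Numerical choices and degenerate inputs

* Permutation p-values are add-one smoothed and never 0; the minimum is
  `1/(n_perm + 1)`.
* `power_at()` errors for frequencies outside the PSD grid; sampling
  rates too low for the 300 Hz band edge clip it to `0.45·fs` with a
  warning rather than failing.
* Constant groups in amplitude normalization map to the maximum (log10
  = 0) with a warning; a zero-variance IED group test reports p = 1
  with a warning; empty spike trains yield NA vector strength.
* Fractional samples-per-cycle (e.g. 5.5 Hz at 500 Hz sampling) are
  handled by per-window rounding of the window start, so cycle windows
  never drift by more than half a sample.
* Seeds: every stochastic routine takes an explicit seed (or inherits
  the caller's RNG state) through `withr`, and sessions are
  bit-reproducible given (ground truth, trials, fs, seed).

# Known limitations

* The PLV noise floor for finite trial counts is positive
  (`~sqrt(pi)/2/sqrt(n)` under the null); the Rayleigh test, not the
  raw PLV, carries the significance decision.
* The superposition simulation inherits summed background noise at the
  stimulation frequency (discussed above); comparisons are meaningful
  for clearly responsive contacts.
* The spectral parameterization, like any aperiodic-plus-peaks fit, can
  absorb very broad oscillations into the aperiodic component near the
  range edges; peak recovery is validated for centers 6–45 Hz.
* Anatomical assignment consumes a labeled voxel grid; registration,
  segmentation and surface-based network labels are upstream inputs,
  not package functionality.
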