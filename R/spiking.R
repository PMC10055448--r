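#' Classify a spike-sorted group as single unit, multi-unit, or artifact
#'
#' Codifies the unit-classification decision table: a group is a single
#' unit if it satisfies all single-unit criteria, a multi-unit if it
#' meets none of the artifact criteria (but fails at least one
#' single-unit criterion), and an artifact otherwise. Artifact criteria:
#' artifact-looking waveform; firing rate <= 0.05 spikes/s; fraction of
#' inter-event intervals under 3 ms >= 0.1; narrowing of the waveform
#' density's main peak; >= 4 local peaks after the main waveform peak.
#' Single-unit criteria: non-artifactual waveform, rate > 0.05,
#' ISI-fraction < 0.05, no narrowing, < 3 post-peak local peaks, and a
#' unimodal event-amplitude distribution. The visual-inspection criteria
#' are consumed as precomputed boolean/ordinal features.
#'
#' @param waveform_artifactual logical: waveform looks like artifact.
#' @param firing_rate spikes/s.
#' @param frac_isi_lt_3ms fraction of inter-event intervals < 3 ms.
#' @param narrowing logical: main density peak narrows.
#' @param n_post_peak_local_peaks integer count of local peaks after the
#'   main peak.
#' @param amplitude_distribution "unimodal" or "multimodal".
#' @return "single", "multi", or "artifact".
#' @export
classify_unit <- function(waveform_artifactual, firing_rate,
                          frac_isi_lt_3ms, narrowing,
                          n_post_peak_local_peaks,
                          amplitude_distribution = c("unimodal",
                                                     "multimodal")) {
  amplitude_distribution <- match.arg(amplitude_distribution)
  stopifnot(firing_rate >= 0, frac_isi_lt_3ms >= 0, frac_isi_lt_3ms <= 1)
  artifact <- waveform_artifactual || firing_rate <= 0.05 ||
    frac_isi_lt_3ms >= 0.1 || narrowing || n_post_peak_local_peaks >= 4
  if (artifact) return("artifact")
  single <- firing_rate > 0.05 && frac_isi_lt_3ms < 0.05 &&
    n_post_peak_local_peaks < 3 &&
    amplitude_distribution == "unimodal"
  if (single) "single" else "multi"
}

#' Peristimulus-time histogram over two stimulus cycles
#'
#' Each stimulation trial is re-segmented into windows of two stimulus
#' cycles with one overlapping cycle between consecutive windows, as for
#' the evoked-potential average; spikes are binned by time within the
#' window and converted to firing rate. For the random condition use
#' `f_stim = 40` (cycles are consecutive 25 ms segments).
#'
#' @param spike_times spike times, seconds.
#' @param trials a [trial_table()] or a subset of its rows (stimulation
#'   trials of one condition).
#' @param f_stim stimulation frequency, Hz.
#' @param n_bins bins across the two-cycle window (default 40, i.e.
#'   20 per cycle).
#' @return list of class `cycle_psth`: `counts`, `rate` (spikes/s per
#'   bin), `bin_centers` (s), `n_windows`, `frac_empty`.
#' @export
cycle_psth <- function(spike_times, trials, f_stim, n_bins = 40) {
  stopifnot(f_stim > 0, n_bins >= 2)
  period <- 1 / f_stim
  wlen <- 2 * period
  counts <- numeric(n_bins)
  n_windows <- 0L
  for (r in seq_len(nrow(trials))) {
    o <- trials$onset_s[r]
    dur <- trials$duration_s[r]
    n_win <- floor(dur * f_stim) - 1
    if (n_win < 1) next
    n_windows <- n_windows + n_win
    sp <- spike_times[spike_times >= o & spike_times < o + dur] - o
    if (!length(sp)) next
    for (w in seq_len(n_win) - 1L) {
      s0 <- w * period
      inw <- sp[sp >= s0 & sp < s0 + wlen]
      if (length(inw)) {
        b <- pmin(floor((inw - s0) / wlen * n_bins) + 1L, n_bins)
        counts <- counts + tabulate(b, n_bins)
      }
    }
  }
  bin_w <- wlen / n_bins
  structure(list(counts = counts,
                 rate = counts / (n_windows * bin_w),
                 bin_centers = (seq_len(n_bins) - 0.5) * bin_w,
                 n_windows = n_windows,
                 frac_empty = mean(counts == 0)),
            class = "cycle_psth")
}

#' Spike-count inclusion rule across conditions
#'
#' A unit is excluded (too few spikes to assess modulation) only if, in
#' every condition, more than `max_frac_empty` of its PSTH bins are
#' empty.
#'
#' @param psths list of [cycle_psth()] results, one per condition.
#' @param max_frac_empty threshold (default 0.2).
#' @return TRUE if the unit is included.
#' @export
include_unit <- function(psths, max_frac_empty = 0.2) {
  fr <- vapply(psths, function(p) p$frac_empty, numeric(1))
  !all(fr > max_frac_empty)
}

#' Vector strength and Rayleigh statistic of stimulus-phase locking
#'
#' Spike phases are taken relative to the stimulus cycle,
#' `theta_j = 2 pi ((t_j - onset) mod T) / T`, pooled over the
#' stimulation trials of one condition. Vector strength is the modulus
#' of the mean unit phasor; the Rayleigh statistic `Z = n VS^2` tests
#' phase uniformity.
#'
#' @param spike_times spike times, seconds.
#' @param trials stimulation trials of one condition (a
#'   [trial_table()] subset).
#' @param f_stim stimulation frequency, Hz.
#' @return list: `vs`, `rayleigh_z`, `rayleigh_p`, `n_spikes`,
#'   `mean_phase` (radians).
#' @export
vector_strength <- function(spike_times, trials, f_stim) {
  stopifnot(f_stim > 0)
  phases <- c()
  for (r in seq_len(nrow(trials))) {
    o <- trials$onset_s[r]
    sp <- spike_times[spike_times >= o &
                        spike_times < o + trials$duration_s[r]]
    phases <- c(phases, 2 * pi * (((sp - o) * f_stim) %% 1))
  }
  n <- length(phases)
  if (n == 0) {
    return(list(vs = NA_real_, rayleigh_z = NA_real_,
                rayleigh_p = NA_real_, n_spikes = 0L,
                mean_phase = NA_real_))
  }
  mv <- mean(exp(1i * phases))
  rt <- rayleigh_test(n = n, r = Mod(mv))
  list(vs = rt$r, rayleigh_z = rt$z, rayleigh_p = rt$p, n_spikes = n,
       mean_phase = Arg(mv))
}

#' Invert vector strength to a von Mises concentration
#'
#' For spikes with von Mises phase modulation, the expected vector
#' strength is `I1(kappa) / I0(kappa)`; this solves that relation
#' numerically for `kappa` given an observed VS.
#'
#' @param vs vector strength in [0, 1).
#' @return estimated concentration `kappa`.
#' @export
vs_to_kappa <- function(vs) {
  stopifnot(vs >= 0, vs < 1)
  if (vs == 0) return(0)
  stats::uniroot(function(k) besselI(k, 1) / besselI(k, 0) - vs,
                 c(1e-8, 500), tol = 1e-10)$root
}
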