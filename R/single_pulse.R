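#' Single-pulse evoked potential extraction
#'
#' High-pass filters the recording at 0.1 Hz (zero-phase Butterworth,
#' order 4, realized as a biquad cascade), segments it into 1 s trials
#' with 0.25 s pads on both sides (-0.25 to +1.25 s around pulse onset),
#' subtracts each trial's mean over the 0.25 s pre-onset window, and
#' returns the time-locked average and SEM per channel.
#'
#' @param rec a `flicker_recording`.
#' @param pulse_onsets pulse onset times, seconds. Inter-pulse intervals
#'   must be at least the paradigm minimum of 987.5 ms, so one pulse's
#'   response window cannot reach past the next pulse's response onset
#'   by more than the pulse width.
#' @param pre,post window before/after onset, seconds (0.25 and 1.25).
#' @return list of class `pulse_ep`: `time` (s, relative to onset),
#'   `mean` and `sem` (channels x time), `trials` (trials x channels x
#'   time), `fs`, `contact_id`.
#' @export
pulse_ep <- function(rec, pulse_onsets, pre = 0.25, post = 1.25) {
  stopifnot(inherits(rec, "flicker_recording"), length(pulse_onsets) >= 2)
  if (any(diff(sort(pulse_onsets)) < 0.9875 - 1e-9)) {
    stop("inter-pulse intervals below 987.5 ms: response segments overlap")
  }
  fs <- rec$fs
  keep <- !rec$channels$excluded
  hp <- butter_sos(4, 0.1, fs, "high")
  x <- filtfilt_sos(rec$samples[keep, , drop = FALSE], hp)
  if (!is.matrix(x)) x <- matrix(x, nrow = sum(keep))
  n_pre <- round(pre * fs)
  n_post <- round(post * fs)
  seg_len <- n_pre + n_post
  n_ch <- nrow(x)
  trials <- array(NA_real_, c(length(pulse_onsets), n_ch, seg_len))
  for (j in seq_along(pulse_onsets)) {
    i0 <- round(pulse_onsets[j] * fs) - n_pre
    if (i0 < 0 || i0 + seg_len > ncol(x)) {
      stop("pulse at t = ", pulse_onsets[j], " s exceeds recording bounds")
    }
    seg <- x[, (i0 + 1):(i0 + seg_len), drop = FALSE]
    bl <- rowMeans(seg[, seq_len(n_pre), drop = FALSE])
    trials[j, , ] <- seg - bl
  }
  m <- apply(trials, c(2, 3), mean)
  s <- apply(trials, c(2, 3), stats::sd) / sqrt(length(pulse_onsets))
  structure(list(time = (seq_len(seg_len) - 1 - n_pre) / fs,
                 mean = m, sem = s, trials = trials, fs = fs,
                 contact_id = rec$channels$contact_id[keep]),
            class = "pulse_ep")
}

#' Peak amplitude of a single-pulse EP
#'
#' Absolute maximum of the trial-averaged response between stimulus
#' onset and 1 s after onset.
#'
#' @param ep a [pulse_ep()] result.
#' @return named numeric, one amplitude (uV) per channel.
#' @export
pulse_amplitude <- function(ep) {
  idx <- ep$time >= 0 & ep$time <= 1
  a <- apply(abs(ep$mean[, idx, drop = FALSE]), 1, max)
  names(a) <- ep$contact_id
  a
}

#' Permutation significance of a single-pulse EP vs the occluded control
#'
#' Test statistic: RMS of the trial-averaged stimulation trace over
#' 0-1 s post-onset minus the RMS of the trial-averaged occluded-control
#' trace over the same window. One-sided random permutation test of the
#' trial labels (default 500 iterations), add-one smoothed.
#'
#' @param stim_trials,occluded_trials trials x time matrices covering
#'   the 0-1 s post-onset window (single channel).
#' @param n_perm permutations (default 500).
#' @param seed RNG seed.
#' @return list: `statistic` (uV), `p_perm`.
#' @export
pulse_significance <- function(stim_trials, occluded_trials, n_perm = 500,
                               seed = NULL) {
  stopifnot(is.matrix(stim_trials), is.matrix(occluded_trials),
            nrow(stim_trials) >= 2, nrow(occluded_trials) >= 2,
            ncol(stim_trials) == ncol(occluded_trials))
  if (!is.null(seed)) withr::local_seed(seed)
  rms <- function(v) sqrt(mean(v^2))
  all_tr <- rbind(stim_trials, occluded_trials)
  na <- nrow(stim_trials)
  n <- nrow(all_tr)
  col_tot <- colSums(all_tr)
  obs <- rms(colMeans(stim_trials)) - rms(colMeans(occluded_trials))
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    sel <- sample.int(n, na)
    ma <- colSums(all_tr[sel, , drop = FALSE]) / na
    mb <- (col_tot - ma * na) / (n - na)
    if (rms(ma) - rms(mb) >= obs - 1e-12) cnt <- cnt + 1L
  }
  list(statistic = obs, p_perm = (1 + cnt) / (n_perm + 1))
}

#' Extract the 0-1 s post-onset trial matrix for one channel
#' @param ep a [pulse_ep()] result.
#' @param channel channel index or contact id.
#' @return trials x time matrix (0 to 1 s post-onset).
#' @export
pulse_window <- function(ep, channel = 1) {
  if (is.character(channel)) channel <- match(channel, ep$contact_id)
  idx <- which(ep$time >= 0 & ep$time <= 1)
  matrix(ep$trials[, channel, idx], dim(ep$trials)[1])
}

#' Min-max normalization of response amplitudes with log10 transform
#'
#' Within each group (conventionally one subject x modality), amplitudes
#' are mapped affinely so the group minimum becomes 0.001 and the
#' maximum becomes 1, then log10-transformed — giving values in
#' [-3, 0]. A constant or singleton group cannot be scaled and maps to
#' the maximum (0 after log), with a warning.
#'
#' @param values numeric amplitudes.
#' @param groups grouping vector (same length), or NULL for one group.
#' @return numeric, log10 of normalized values, in [-3, 0].
#' @export
normalize_amplitudes <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep(1, length(values))
  out <- rep(NA_real_, length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- values[idx]
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("group ", g, " is constant; mapped to maximum (log10 = 0)")
      out[idx] <- 0
    } else {
      out[idx] <- log10(0.001 + (v - rng[1]) / diff(rng) * (1 - 0.001))
    }
  }
  out
}

#' Simulate 40 Hz flicker trials by linear superposition of pulse EPs
#'
#' The linear-superposition counterfactual: if the steady-state evoked
#' potential were just overlapping single-pulse responses, a 40 Hz trial
#' would equal single-pulse EPs summed every 25 ms. For each simulated
#' trial, one recorded single-pulse trial (its 0-1 s post-onset trace)
#' is drawn with replacement at every 25 ms grid point and added at that
#' offset; tails extending past the trial end are truncated. The
#' simulated trials are then quantified exactly like recorded flicker
#' trials (fold-change at 40 Hz against the same baseline trials).
#'
#' @param pulse_trials trials x time matrix of 0-1 s post-onset
#'   single-pulse responses (one channel), at sampling rate `fs`.
#' @param fs sampling rate, Hz.
#' @param f simulated stimulation frequency (default 40 Hz; the pulse
#'   grid step is `1/f`).
#' @param n_sim_trials simulated trials (default 15).
#' @param trial_len simulated trial length, s (default 10).
#' @param seed RNG seed for the trial draws.
#' @return `trial_tensor` (trials x 1 x time) of simulated flicker
#'   trials, tagged `simulated = TRUE`.
#' @export
simulate_superposition <- function(pulse_trials, fs, f = 40,
                                   n_sim_trials = 15, trial_len = 10,
                                   seed = NULL) {
  stopifnot(is.matrix(pulse_trials), nrow(pulse_trials) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  n_time <- round(trial_len * fs)
  n_slots <- floor(trial_len * f)
  ep_len <- ncol(pulse_trials)
  sim <- array(0, c(n_sim_trials, 1, n_time))
  for (tr in seq_len(n_sim_trials)) {
    v <- numeric(n_time)
    draws <- sample.int(nrow(pulse_trials), n_slots, replace = TRUE)
    for (s in seq_len(n_slots)) {
      i0 <- round((s - 1) * fs / f)
      klen <- min(ep_len, n_time - i0)
      if (klen > 0) {
        v[(i0 + 1):(i0 + klen)] <- v[(i0 + 1):(i0 + klen)] +
          pulse_trials[draws[s], seq_len(klen)]
      }
    }
    sim[tr, 1, ] <- v
  }
  tt <- new_trial_tensor(sim, fs, sprintf("simulated@%g", f), 0,
                         onset_samples = rep(NA_integer_, n_sim_trials),
                         trial_ids = seq_len(n_sim_trials),
                         contact_ids = "sim")
  attr(tt, "simulated") <- TRUE
  tt
}

#' Classify a contact's response profile
#'
#' Crosses single-pulse and steady-state (flicker) significance at the
#' matched modality into the four response classes.
#'
#' @param pulse_p single-pulse permutation p-value.
#' @param flicker_p steady-state permutation p-value.
#' @param alpha significance level (default 0.05).
#' @return one of "both", "flicker_only", "pulse_only", "none".
#' @export
classify_response <- function(pulse_p, flicker_p, alpha = 0.05) {
  sp <- pulse_p < alpha
  sf <- flicker_p < alpha
  ifelse(sp & sf, "both",
         ifelse(sf, "flicker_only",
                ifelse(sp, "pulse_only", "none")))
}

#' Generate a synthetic single-pulse session
#'
#' Pulses with inter-pulse intervals drawn uniformly between 987.5 and
#' 1487.5 ms; each pulse adds the ground-truth kernel (scaled by the
#' adapting gain's single-pulse value of 1) on top of the 1/f
#' background. With `response = FALSE` the session is an occluded-style
#' control: identical background, no evoked response.
#'
#' @param gt a [ground_truth()].
#' @param n_pulses number of pulses (default 200).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @param response add the pulse-evoked kernel (default TRUE).
#' @return list: `rec` (a `flicker_recording`), `onsets` (s).
#' @export
make_pulse_session <- function(gt, n_pulses = 200, fs = 500, seed = 1L,
                               response = TRUE) {
  stopifnot(inherits(gt, "flicker_ground_truth"))
  withr::local_seed(seed)
  ipi <- stats::runif(n_pulses, 0.9875, 1.4875)
  onsets <- 2 + cumsum(c(0, ipi[-n_pulses]))
  n_time <- round((max(onsets) + 2) * fs)
  m <- stats::nextn(n_time, 2)
  fold_sym <- pmin((0:(m - 1)) / m * fs, fs - (0:(m - 1)) / m * fs)
  samples <- matrix(0, gt$n_channels, n_time)
  ker <- gt_kernel(gt, fs)
  for (i in seq_len(gt$n_channels)) {
    h <- sqrt(gt_psd_model(gt, fold_sym, i) * fs / 2)
    w <- stats::fft(stats::rnorm(m)) * h
    x <- Re(stats::fft(w, inverse = TRUE))[seq_len(n_time)] / m
    if (response && gt$response_mode[i] != "none") {
      for (o in onsets) {
        j0 <- round(o * fs)
        x[(j0 + 1):(j0 + length(ker))] <-
          x[(j0 + 1):(j0 + length(ker))] + ker
      }
    }
    samples[i, ] <- x
  }
  channels <- data.frame(
    contact_id = sprintf("c%02d", seq_len(gt$n_channels)),
    probe_id = sprintf("p%02d", seq_len(gt$n_channels)),
    probe_index = 1L, excluded = FALSE, stringsAsFactors = FALSE)
  list(rec = new_recording(samples, fs, channels), onsets = onsets)
}
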