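#' Stimulus waveforms for flicker and pulse paradigms
#'
#' Periodic flicker is a 50% duty-cycle square wave (a 40 Hz train is
#' 12.5 ms on / 12.5 ms off). The random (non-periodic) condition is a
#' train of 12.5 ms pulses with inter-pulse intervals drawn uniformly
#' between 0 and 25 ms, so its mean pulse period matches the 40 Hz
#' train. Auditory stimuli are a 7 kHz tone amplitude-modulated by a
#' pseudo-square envelope with ~1.6 ms ramps; the carrier is only
#' rendered when the sampling rate can represent it (fs >= 14 kHz) —
#' at LFP sampling rates the envelope is the relevant signal and is what
#' all analyses consume.
#'
#' @param modality "visual", "audiovisual" or "auditory".
#' @param frequency numeric Hz, or `"random"`.
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed (used by the random condition).
#' @return list: `envelope` (0/1 on-off), `signal` (envelope, or
#'   carrier-modulated tone for auditory at audio rates), `onsets`
#'   (pulse onset times, s, relative to stimulus start), `fs`,
#'   `frequency`.
#' @export
make_stimulus <- function(modality, frequency, duration, fs, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  pulse_w <- 0.0125
  if (identical(frequency, "random") || is.na(suppressWarnings(as.numeric(frequency)))) {
    onsets <- c()
    tc <- 0
    while (tc + pulse_w <= duration + 1e-12) {
      onsets <- c(onsets, tc)
      tc <- tc + pulse_w + stats::runif(1, 0, 0.025)
    }
    env <- numeric(n)
    for (o in onsets) {
      i0 <- floor(o * fs) + 1
      i1 <- min(n, ceiling((o + pulse_w) * fs))
      env[i0:i1] <- 1
    }
    frequency <- "random"
  } else {
    f <- as.numeric(frequency)
    stopifnot(f > 0, f <= fs / 4)
    phase <- (t * f) %% 1
    env <- as.numeric(phase < 0.5)
    onsets <- seq(0, duration - 1 / (2 * f) + 1e-12, by = 1 / f)
    onsets <- onsets[onsets < duration]
  }
  sig <- env
  if (modality %in% c("auditory", "audiovisual") && fs >= 14000) {
    ramp_n <- max(1L, round(0.0016 * fs))
    env_r <- stats::filter(env, rep(1 / ramp_n, ramp_n), sides = 2)
    env_r[is.na(env_r)] <- 0
    sig <- as.numeric(env_r) * sin(2 * pi * 7000 * t)
  }
  list(envelope = env, signal = sig, onsets = onsets, fs = fs,
       frequency = frequency)
}

#' Ground-truth parameters for a synthetic flicker session
#'
#' Defines the generative model the analyses are validated against:
#' a 1/f aperiodic background with optional Gaussian oscillation bumps
#' per channel; a condition-locked sinusoidal steady-state component
#' whose amplitude is calibrated so that the injected power fold-change
#' at the stimulation frequency equals `fold_change` exactly (in
#' expectation under the package's own multitaper estimator); per-trial
#' stimulus phase jitter; and pulse-evoked kernel responses in one of
#' four modes. `linear_superposition` convolves the pulse train with a
#' damped-oscillation kernel; `resonant` additionally passes the
#' response through a second-order resonator (center, Q) so that the
#' response amplitude depends on stimulation frequency; `adapting`
#' scales the k-th pulse in a trial by `g_inf + (1 - g_inf) *
#' exp(-k / tau)` so the steady-state response is weaker than the
#' single-pulse response predicts; `none` adds no kernel response.
#'
#' Scalar parameters are recycled across channels; `peaks` is either one
#' list of `c(center, height, width)` peaks shared by all channels or a
#' list of such lists, one per channel. Peak `height` is in log10 power
#' above the aperiodic fit and `width` is twice the Gaussian standard
#' deviation, matching the reporting convention of
#' [detect_endogenous()].
#'
#' @param n_channels number of channels.
#' @param aperiodic_offset log10 power density at 1 Hz (per channel).
#' @param aperiodic_exponent 1/f slope (per channel).
#' @param peaks endogenous oscillations, see Details.
#' @param fold_change target power fold-change of the sinusoidal
#'   steady-state component at the stimulation frequency (0 = none).
#' @param phase_jitter_sd per-trial stimulus phase jitter SD, radians.
#' @param response_mode "none", "linear_superposition", "resonant" or
#'   "adapting" (per channel).
#' @param kernel damped-oscillation pulse kernel: list
#'   `(amp, freq, decay)` — amplitude (uV), oscillation frequency (Hz),
#'   exponential decay time constant (s); kernel length 1 s.
#' @param resonator list `(center, q)`: resonator center frequency (Hz)
#'   and quality factor (resonant mode).
#' @param adapt list `(g_inf, tau)`: steady-state gain and adaptation
#'   time constant in pulses (adapting mode).
#' @param spike list `(rate, kappa, pref_phase)`: baseline firing rate
#'   (spikes/s), von Mises concentration of phase modulation, preferred
#'   stimulus phase (radians).
#' @param ied list `(rate_stim, rate_baseline, channel_mean, p_noise,
#'   noise_channels)`: IED event rates (events/s) during stimulation and
#'   baseline, mean number of extra channels per event, probability of a
#'   wide "noise" event, and its channel count.
#' @return object of class `flicker_ground_truth`.
#' @export
ground_truth <- function(n_channels = 1,
                         aperiodic_offset = 1,
                         aperiodic_exponent = 1.5,
                         peaks = list(),
                         fold_change = 0,
                         phase_jitter_sd = 0,
                         response_mode = "none",
                         kernel = list(amp = 20, freq = 12, decay = 0.05),
                         resonator = list(center = 40, q = 5),
                         adapt = list(g_inf = 0.2, tau = 3),
                         spike = list(rate = 5, kappa = 0, pref_phase = 0),
                         ied = list(rate_stim = 0.5, rate_baseline = 0.5,
                                    channel_mean = 1.5, p_noise = 0,
                                    noise_channels = 12)) {
  stopifnot(n_channels >= 1, all(fold_change >= 0),
            all(phase_jitter_sd >= 0), spike$kappa >= 0, spike$rate >= 0,
            ied$rate_stim >= 0, ied$rate_baseline >= 0)
  response_mode <- rep_len(response_mode, n_channels)
  stopifnot(all(response_mode %in%
                  c("none", "linear_superposition", "resonant", "adapting")))
  per_channel_peaks <- length(peaks) && is.list(peaks[[1]]) &&
    (length(peaks[[1]]) == 0 || is.numeric(peaks[[1]][[1]]) &&
       length(peaks[[1]][[1]]) == 3)
  if (!per_channel_peaks) peaks <- rep(list(peaks), n_channels)
  stopifnot(length(peaks) == n_channels)
  for (pk in unlist(peaks, recursive = FALSE)) {
    stopifnot(length(pk) == 3, pk[2] >= 0, pk[3] > 0)
  }
  structure(list(
    n_channels = n_channels,
    aperiodic_offset = rep_len(aperiodic_offset, n_channels),
    aperiodic_exponent = rep_len(aperiodic_exponent, n_channels),
    peaks = peaks,
    fold_change = rep_len(fold_change, n_channels),
    phase_jitter_sd = rep_len(phase_jitter_sd, n_channels),
    response_mode = response_mode,
    kernel = kernel, resonator = resonator, adapt = adapt,
    spike = spike, ied = ied), class = "flicker_ground_truth")
}

# baseline PSD model (linear power density) at frequencies f, channel i
gt_psd_model <- function(gt, f, i) {
  f <- pmax(f, 1e-3)
  lg <- gt$aperiodic_offset[i] - gt$aperiodic_exponent[i] * log10(f)
  for (pk in gt$peaks[[i]]) {
    lg <- lg + pk[2] * exp(-(f - pk[1])^2 / (2 * (pk[3] / 2)^2))
  }
  10^lg
}

# damped-oscillation pulse kernel, 1 s long
gt_kernel <- function(gt, fs) {
  t <- (seq_len(round(fs)) - 1) / fs
  gt$kernel$amp * exp(-t / gt$kernel$decay) * sin(2 * pi * gt$kernel$freq * t)
}

# two-pole resonator, unit gain at its center frequency
resonator_filter <- function(x, center, q, fs) {
  w0 <- 2 * pi * center / fs
  r <- exp(-pi * center / (q * fs))
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- Mod(1 + a[2] * exp(-1i * w0) + a[3] * exp(-2i * w0))
  as.numeric(stats::filter(x * g, -a[2:3], method = "recursive"))
}

#' Generate a synthetic multichannel LFP session with known ground truth
#'
#' Baseline activity is Gaussian noise spectrally shaped (by FFT
#' filtering) to the per-channel aperiodic-plus-peaks power spectrum of
#' the ground truth; endogenous oscillations are thus narrowband noise
#' with naturally drifting phase. During stimulation trials the
#' condition-locked components described in [ground_truth()] are added.
#' Each channel is placed on its own probe: synthetic sessions emulate
#' already-referenced, independent recording locations.
#'
#' @param gt a [ground_truth()].
#' @param trials a [trial_table()].
#' @param fs sampling rate, Hz.
#' @param seed RNG seed; the session is bit-reproducible given
#'   (gt, trials, fs, seed).
#' @param tail_pad extra seconds of signal after the last trial
#'   (default 2; 2 s are also required before the first trial onset).
#' @param return_clean also return the noiseless added response.
#' @return list of class `flicker_session`: `rec`
#'   (a `flicker_recording`), `trials`, `gt`, `expected` (data.frame of
#'   expected power fold-change per channel and stimulation condition,
#'   computed from the noiseless response via the package's multitaper
#'   estimator), and optionally `clean` (channels x time matrix).
#' @export
make_lfp_session <- function(gt, trials, fs, seed = 1L, tail_pad = 2,
                             return_clean = FALSE) {
  stopifnot(inherits(gt, "flicker_ground_truth"))
  withr::local_seed(seed)
  n_time <- round((max(trials$onset_s + trials$duration_s) + tail_pad) * fs)
  m <- stats::nextn(n_time, 2)
  freq_all <- (0:(m - 1)) / m * fs
  fold_sym <- pmin(freq_all, fs - freq_all)
  samples <- matrix(0, gt$n_channels, n_time)
  clean <- matrix(0, gt$n_channels, n_time)
  conds <- condition_of(trials)
  is_stim <- trials$modality != "none" & trials$frequency != "baseline"
  stim_rows <- which(is_stim)
  # per-trial random draws (shared across channels, like a real stimulus)
  jitter_z <- stats::rnorm(nrow(trials))
  stim_cache <- list()
  for (r in stim_rows) {
    key <- paste0(conds[r], "#", r)
    stim_cache[[key]] <- make_stimulus(trials$modality[r],
                                       trials$frequency[r],
                                       trials$duration_s[r], fs)
  }
  for (i in seq_len(gt$n_channels)) {
    h <- sqrt(gt_psd_model(gt, fold_sym, i) * fs / 2)
    w <- stats::fft(stats::rnorm(m)) * h
    x <- Re(stats::fft(w, inverse = TRUE)) / m
    x <- x[seq_len(n_time)]
    add <- numeric(n_time)
    for (r in stim_rows) {
      f_num <- suppressWarnings(as.numeric(trials$frequency[r]))
      dur <- trials$duration_s[r]
      n_tr <- round(dur * fs)
      i0 <- round(trials$onset_s[r] * fs)
      idx <- (i0 + 1):(i0 + n_tr)
      tloc <- (seq_len(n_tr) - 1) / fs
      if (!is.na(f_num) && gt$fold_change[i] > 0) {
        amp <- ss_amplitude(gt$fold_change[i],
                            gt_psd_model(gt, f_num, i), fs, n_tr)
        phi <- jitter_z[r] * gt$phase_jitter_sd[i]
        add[idx] <- add[idx] + amp * sin(2 * pi * f_num * tloc + phi)
      }
      mode <- gt$response_mode[i]
      if (mode != "none") {
        st <- stim_cache[[paste0(conds[r], "#", r)]]
        ker <- gt_kernel(gt, fs)
        resp <- numeric(n_tr)
        for (k in seq_along(st$onsets)) {
          g <- if (mode == "adapting") {
            gt$adapt$g_inf + (1 - gt$adapt$g_inf) * exp(-(k - 1) / gt$adapt$tau)
          } else 1
          j0 <- round(st$onsets[k] * fs)
          klen <- min(length(ker), n_tr - j0)
          if (klen > 0) {
            resp[(j0 + 1):(j0 + klen)] <- resp[(j0 + 1):(j0 + klen)] +
              g * ker[seq_len(klen)]
          }
        }
        if (mode == "resonant") {
          resp <- resonator_filter(resp, gt$resonator$center,
                                   gt$resonator$q, fs)
        }
        add[idx] <- add[idx] + resp
      }
    }
    samples[i, ] <- x + add
    clean[i, ] <- add
  }
  channels <- data.frame(
    contact_id = sprintf("c%02d", seq_len(gt$n_channels)),
    probe_id = sprintf("p%02d", seq_len(gt$n_channels)),
    probe_index = 1L, excluded = FALSE, stringsAsFactors = FALSE)
  rec <- new_recording(samples, fs, channels)
  expected <- gt_expected_fold(gt, trials, clean, fs)
  out <- list(rec = rec, trials = trials, gt = gt, expected = expected)
  if (return_clean) out$clean <- clean
  structure(out, class = "flicker_session")
}

# amplitude of an on-grid sinusoid whose multitaper power at its bin is
# target * baseline_psd: P_sin = A^2 * mean_k (sum_t h_k)^2 / (2 fs)
ss_amplitude <- function(target_fold, baseline_psd, fs, n) {
  h <- dpss_tapers(n)
  s2 <- mean(colSums(h)^2)
  sqrt(2 * fs * target_fold * baseline_psd / s2)
}

# expected fold-change per channel x condition, from the noiseless
# response: multitaper power of the clean trace at the stimulation bin,
# averaged over trials, relative to the model baseline PSD
gt_expected_fold <- function(gt, trials, clean, fs) {
  conds <- condition_of(trials)
  stim_conds <- unique(conds[trials$modality != "none" &
                               trials$frequency != "baseline"])
  out <- list()
  for (cond in stim_conds) {
    f_num <- condition_frequency(cond)
    f_eval <- if (is.na(f_num)) 40 else f_num
    rows <- which(conds == cond)
    for (i in seq_len(gt$n_channels)) {
      p_tr <- vapply(rows, function(r) {
        i0 <- round(trials$onset_s[r] * fs)
        n_tr <- round(trials$duration_s[r] * fs)
        seg <- clean[i, (i0 + 1):(i0 + n_tr)]
        if (all(seg == 0)) return(0)
        ps <- multitaper_psd(seg, fs, fmin = 0, fmax = fs / 2)
        ps$psd[which.min(abs(ps$freq - f_eval))]
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        contact_id = sprintf("c%02d", i), condition = cond,
        expected_fold = mean(p_tr) / gt_psd_model(gt, f_eval, i),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate a phase-modulated synthetic spike train
#'
#' Inhomogeneous Poisson process with von Mises rate modulation by
#' stimulus phase during stimulation trials:
#' `lambda(t) = r0 * exp(kappa * cos(theta(t) - phi0)) / I0(kappa)`,
#' where `theta(t)` is the instantaneous stimulus phase. `kappa = 0`
#' gives a homogeneous Poisson train at rate `r0` (as do baseline trials
#' and inter-trial gaps).
#'
#' @param gt a [ground_truth()] (uses `gt$spike`).
#' @param trials a [trial_table()].
#' @param seed RNG seed.
#' @return sorted spike times, seconds.
#' @export
make_spikes <- function(gt, trials, seed = 1L) {
  withr::local_seed(seed)
  r0 <- gt$spike$rate
  kap <- gt$spike$kappa
  phi0 <- gt$spike$pref_phase
  if (r0 == 0) return(numeric(0))
  t_end <- max(trials$onset_s + trials$duration_s)
  conds <- condition_of(trials)
  f_num <- condition_frequency(conds)
  spikes <- list()
  # homogeneous background over the whole session outside stim trials
  n_bg <- stats::rpois(1, r0 * t_end)
  bg <- stats::runif(n_bg, 0, t_end)
  in_stim <- rep(FALSE, n_bg)
  for (r in which(!is.na(f_num))) {
    in_stim <- in_stim | (bg >= trials$onset_s[r] &
                            bg < trials$onset_s[r] + trials$duration_s[r])
  }
  spikes[[1]] <- bg[!in_stim]
  i0k <- besselI(kap, 0)
  lam_max <- r0 * exp(kap) / i0k
  for (r in which(!is.na(f_num))) {
    o <- trials$onset_s[r]
    dur <- trials$duration_s[r]
    n_cand <- stats::rpois(1, lam_max * dur)
    tc <- stats::runif(n_cand, 0, dur)
    theta <- 2 * pi * f_num[r] * tc
    keep <- stats::runif(n_cand) < exp(kap * (cos(theta - phi0) - 1))
    spikes[[length(spikes) + 1]] <- o + tc[keep]
  }
  sort(unlist(spikes))
}

#' Generate synthetic interictal-discharge events
#'
#' Piecewise-constant-rate Poisson event stream: `rate_stim` events/s
#' during stimulation trials, `rate_baseline` during baseline trials
#' (no events outside trials). Each event is assigned a random channel
#' subset of size `1 + Poisson(channel_mean)`; with probability
#' `p_noise` an event is instead a wide "noise" event spanning
#' `noise_channels` channels (for testing the >11-channel rejection).
#'
#' @param gt a [ground_truth()] (uses `gt$ied`).
#' @param trials a [trial_table()].
#' @param n_channels number of channels to draw subsets from.
#' @param seed RNG seed.
#' @return data.frame: `t_s` (seconds, sorted), `channels` (list column
#'   of contact-id character vectors).
#' @export
make_ieds <- function(gt, trials, n_channels = 16, seed = 1L) {
  withr::local_seed(seed)
  p <- gt$ied
  ids <- sprintf("c%02d", seq_len(n_channels))
  times <- list(); chans <- list()
  is_base <- trials$modality == "none" | trials$frequency == "baseline"
  for (r in seq_len(nrow(trials))) {
    rate <- if (is_base[r]) p$rate_baseline else p$rate_stim
    n_ev <- stats::rpois(1, rate * trials$duration_s[r])
    if (n_ev == 0) next
    tev <- sort(stats::runif(n_ev, trials$onset_s[r],
                             trials$onset_s[r] + trials$duration_s[r]))
    for (tv in tev) {
      if (stats::runif(1) < p$p_noise) {
        size <- min(p$noise_channels, n_channels)
      } else {
        size <- min(1 + stats::rpois(1, p$channel_mean), n_channels)
      }
      times[[length(times) + 1]] <- tv
      chans[[length(chans) + 1]] <- sample(ids, size)
    }
  }
  if (!length(times)) {
    return(data.frame(t_s = numeric(0), channels = I(list())))
  }
  ord <- order(unlist(times))
  data.frame(t_s = unlist(times)[ord], channels = I(chans[ord]))
}

#' Build a trial schedule for the flicker paradigms
#'
#' Produces a valid, non-overlapping trial table in which every
#' stimulation trial is immediately followed by a baseline trial of the
#' same duration (the structure both the steady-state and the IED
#' analyses assume). Condition order is randomized.
#'
#' @param conditions character vector of condition labels,
#'   e.g. `c("visual@40", "auditory@5.5", "visual@random")`.
#' @param n_each trials per condition.
#' @param duration trial duration, s (default 10).
#' @param start onset of the first trial, s (default 2; leaves room for
#'   segmentation pads).
#' @param seed RNG seed for the condition order.
#' @return a [trial_table()] with interleaved `none@baseline` trials.
#' @export
make_trial_schedule <- function(conditions, n_each = 15, duration = 10,
                                start = 2, seed = 1L) {
  withr::local_seed(seed)
  stim <- sample(rep(conditions, n_each))
  n <- length(stim)
  onset_stim <- start + (seq_len(n) - 1) * 2 * duration
  onset_base <- onset_stim + duration
  mod <- sub("@.*$", "", stim)
  frq <- sub("^.*@", "", stim)
  trial_table(
    modality = c(mod, rep("none", n)),
    frequency = c(frq, rep("baseline", n)),
    onset_s = c(onset_stim, onset_base),
    duration_s = duration)
}
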