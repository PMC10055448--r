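#' Multitaper power spectral density of trial data
#'
#' Per-trial DPSS multitaper PSD (one-sided, power density in uV^2/Hz)
#' with the estimation settings used throughout the flicker analyses:
#' time-bandwidth product 3, five tapers, reported on a 2-100 Hz grid.
#' A 10 s trial gives a native 0.1 Hz grid, which places every flicker
#' stimulation frequency used here exactly on a bin.
#'
#' @param x a `trial_tensor`, a trials-x-time matrix, or a vector.
#' @param fs sampling rate (ignored when `x` is a `trial_tensor`).
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5).
#' @param fmin,fmax reported frequency range, Hz (defaults 2 and 100;
#'   use `fmin = 0, fmax = fs/2` for the full band).
#' @return list of class `mt_psd`: `freq` (Hz), `psd` — for a tensor an
#'   array trials x channels x freq, for a matrix trials x freq, for a
#'   vector a numeric vector — plus `df` (bin width), `nw`, `k`.
#' @export
multitaper_psd <- function(x, fs = NULL, nw = 3, k = 5, fmin = 2, fmax = 100) {
  if (inherits(x, "trial_tensor")) {
    fs <- x$fs
    d <- dim(x$data)
    n <- d[3]
    grid <- mt_grid(n, fs, fmin, fmax)
    psd <- array(NA_real_, c(d[1], d[2], length(grid$idx)))
    for (tr in seq_len(d[1])) {
      m <- matrix(x$data[tr, , ], nrow = d[2])
      psd[tr, , ] <- mt_core(m, fs, nw, k)[, grid$idx, drop = FALSE]
    }
    dimnames(psd) <- list(NULL, dimnames(x$data)[[2]], NULL)
    return(structure(list(freq = grid$freq, psd = psd, df = grid$df,
                          fs = fs, nw = nw, k = k), class = "mt_psd"))
  }
  stopifnot(!is.null(fs))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  grid <- mt_grid(ncol(x), fs, fmin, fmax)
  psd <- mt_core(x, fs, nw, k)[, grid$idx, drop = FALSE]
  if (vec) psd <- drop(psd)
  structure(list(freq = grid$freq, psd = psd, df = grid$df, fs = fs,
                 nw = nw, k = k), class = "mt_psd")
}

mt_grid <- function(n, fs, fmin, fmax) {
  freq <- (0:(n - 1)) * fs / n
  half <- freq <= fs / 2
  idx <- which(half & freq >= fmin & freq <= fmax)
  list(freq = freq[idx], idx = idx, df = fs / n)
}

# rows of x are signals; returns rows x full frequency grid (one-sided
# density scaling on the kept half)
mt_core <- function(x, fs, nw, k) {
  n <- ncol(x)
  h <- dpss_tapers(n, nw, k)
  out <- matrix(0, nrow(x), n)
  for (j in seq_len(k)) {
    tap <- sweep(x, 2, h[, j], "*")
    ft <- t(stats::mvfft(t(tap)))
    out <- out + Mod(ft)^2
  }
  out <- out * (2 / (fs * k))
  # DC and Nyquist are not doubled
  out[, 1] <- out[, 1] / 2
  if (n %% 2 == 0) out[, n / 2 + 1] <- out[, n / 2 + 1] / 2
  out
}

#' Per-trial power at the stimulation frequency
#'
#' Nearest-bin lookup on the PSD grid (10 s windows give 0.1 Hz native
#' resolution, so the bin error is negligible).
#'
#' @param psd an `mt_psd` from a `trial_tensor`.
#' @param f_stim stimulation frequency, Hz.
#' @return trials x channels matrix of power at the nearest bin.
#' @export
power_at <- function(psd, f_stim) {
  stopifnot(inherits(psd, "mt_psd"), length(dim(psd$psd)) == 3)
  if (f_stim < min(psd$freq) - psd$df / 2 ||
      f_stim > max(psd$freq) + psd$df / 2) {
    stop("f_stim = ", f_stim, " Hz is outside the PSD grid (",
         min(psd$freq), "-", max(psd$freq), " Hz)")
  }
  bin <- which.min(abs(psd$freq - f_stim))
  matrix(psd$psd[, , bin], dim(psd$psd)[1],
         dimnames = list(NULL, dimnames(psd$psd)[[2]]))
}

#' Fold-change in power at the stimulation frequency, with permutation p
#'
#' The steady-state evoked potential amplitude measure:
#' `fold_change = mu_stim / mu_bl - 1`, where `mu_stim` is power at the
#' stimulation frequency averaged across stimulation trials and `mu_bl`
#' the same over an equal number of baseline trials. Significance comes
#' from a one-sided random permutation test of the trial labels on the
#' difference of means `mu_stim - mu_bl` (default 10,000 iterations);
#' the p-value uses add-one smoothing, `p = (1 + #{perm >= obs}) /
#' (n_perm + 1)`, so it is never exactly zero.
#'
#' @param stim_power,baseline_power per-trial power values at the
#'   stimulation frequency (vectors, one value per trial).
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list: `fold_change`, `p_perm`, `mu_stim`, `mu_bl`.
#' @export
fold_change <- function(stim_power, baseline_power, n_perm = 10000,
                        seed = NULL) {
  stopifnot(length(stim_power) >= 1, length(baseline_power) >= 1,
            all(stim_power >= 0), all(baseline_power >= 0))
  mu_s <- mean(stim_power)
  mu_b <- mean(baseline_power)
  obs <- mu_s - mu_b
  p <- perm_p_mean_diff(stim_power, baseline_power, n_perm, seed)
  list(fold_change = mu_s / mu_b - 1, p_perm = p,
       mu_stim = mu_s, mu_bl = mu_b)
}

# One-sided permutation p for mean(A) - mean(B) >= observed, add-one
# smoothed. Vectorized over permutations.
perm_p_mean_diff <- function(a, b, n_perm, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  vals <- c(a, b)
  na <- length(a)
  n <- length(vals)
  obs <- mean(a) - mean(b)
  tot <- sum(vals)
  idx <- replicate(n_perm, sample.int(n, na))
  sum_a <- colSums(matrix(vals[idx], nrow = na))
  stat <- sum_a / na - (tot - sum_a) / (n - na)
  (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
}

#' Trial-averaged evoked response over two stimulus cycles
#'
#' Re-segments each trial into windows of two stimulus cycles with one
#' cycle of overlap between consecutive windows (stride one cycle), and
#' averages all windows across trials; a 10 s trial at 40 Hz yields 399
#' windows. For the random (non-periodic) condition pass `f_stim = 40`:
#' pseudo-cycles are consecutive 25 ms segments.
#'
#' @param seg a filtered, pad-trimmed `trial_tensor`.
#' @param f_stim stimulation frequency, Hz (40 for "random").
#' @return list: `time` (s, 0 to 2 cycles), `mean` and `sem`
#'   (channels x time), `n_windows`.
#' @export
evoked_two_cycle <- function(seg, f_stim) {
  stopifnot(inherits(seg, "trial_tensor"), f_stim > 0)
  fs <- seg$fs
  d <- dim(seg$data)
  period <- fs / f_stim  # samples per cycle, possibly fractional
  win_len <- round(2 * period)
  n_cycles <- floor(d[3] / period)
  n_win <- n_cycles - 1
  stopifnot(n_win >= 1)
  acc <- matrix(0, d[2], win_len)
  acc2 <- matrix(0, d[2], win_len)
  for (tr in seq_len(d[1])) {
    x <- matrix(seg$data[tr, , ], nrow = d[2])
    for (w in seq_len(n_win) - 1L) {
      s0 <- round(w * period)
      if (s0 + win_len > d[3]) next
      wdat <- x[, (s0 + 1):(s0 + win_len), drop = FALSE]
      acc <- acc + wdat
      acc2 <- acc2 + wdat^2
    }
  }
  n_tot <- d[1] * n_win
  m <- acc / n_tot
  v <- pmax(acc2 / n_tot - m^2, 0) * n_tot / max(n_tot - 1, 1)
  list(time = (seq_len(win_len) - 1) / fs, mean = m,
       sem = sqrt(v / n_tot), n_windows = n_tot)
}

#' Inter-trial phase-locking value to the stimulus, with Rayleigh test
#'
#' The stimulus is approximated by a sinusoid at the stimulation
#' frequency (phase zero at trial onset). Each trial is cut into
#' non-overlapping windows of half the sampling rate (0.5 s); in each
#' window the LFP-stimulus phase difference at the stimulation frequency
#' is taken from the cross-spectrum at the nearest FFT bin. The PLV is
#' the modulus of the mean unit phasor pooled over trials and windows
#' (`average = "pooled"`), or of trial means averaged after within-trial
#' averaging (`average = "within_trial"`). Non-uniformity of the
#' trial-mean phase angles is assessed with Rayleigh's test.
#'
#' @param seg a filtered, pad-trimmed `trial_tensor`.
#' @param f_stim stimulation frequency, Hz (must be >= 4 Hz so that it
#'   is resolvable in a 0.5 s window).
#' @param average `"pooled"` (default) or `"within_trial"`.
#' @return list of class `phase_lock`: `plv` (per channel),
#'   `rayleigh_p` (per channel, on trial-mean angles), `trial_angles`
#'   (trials x channels, radians).
#' @export
phase_locking <- function(seg, f_stim,
                          average = c("pooled", "within_trial")) {
  average <- match.arg(average)
  stopifnot(inherits(seg, "trial_tensor"))
  if (f_stim < 4) stop("f_stim must be >= 4 Hz for 0.5 s windows")
  fs <- seg$fs
  d <- dim(seg$data)
  wlen <- round(fs / 2)
  n_win <- floor(d[3] / wlen)
  stopifnot(n_win >= 1)
  freq <- (0:(wlen - 1)) * fs / wlen
  bin <- which.min(abs(freq[1:(floor(wlen / 2) + 1)] - f_stim))
  t_all <- (seq_len(d[3]) - 1) / fs
  stim <- sin(2 * pi * f_stim * t_all)
  trial_mean <- matrix(0i, d[1], d[2])
  pooled <- matrix(0i, 1, d[2])
  for (tr in seq_len(d[1])) {
    x <- matrix(seg$data[tr, , ], nrow = d[2])
    phasor_sum <- rep(0i, d[2])
    for (w in seq_len(n_win)) {
      idx <- ((w - 1) * wlen + 1):(w * wlen)
      xf <- stats::mvfft(t(x[, idx, drop = FALSE]))[bin, ]
      sf <- stats::fft(stim[idx])[bin]
      dphi <- xf * Conj(sf)
      u <- dphi / Mod(dphi)
      u[!is.finite(u)] <- 0i
      phasor_sum <- phasor_sum + u
    }
    trial_mean[tr, ] <- phasor_sum / n_win
    pooled <- pooled + phasor_sum
  }
  plv <- if (average == "pooled") {
    Mod(pooled[1, ]) / (d[1] * n_win)
  } else {
    Mod(colSums(trial_mean / pmax(Mod(trial_mean), 1e-300))) / d[1]
  }
  angles <- Arg(trial_mean)
  ray <- apply(angles, 2, function(a) rayleigh_test(a)$p)
  structure(list(plv = plv, rayleigh_p = ray, trial_angles = angles,
                 n_windows = n_win),
            class = "phase_lock")
}

#' Rayleigh test for non-uniformity of circular data
#'
#' `Z = n * R^2` with mean resultant length `R`; the p-value uses the
#' standard finite-sample approximation
#' `p = exp(-Z) * (1 + (2 Z - Z^2) / (4 n))`, clamped to (0, 1].
#'
#' @param angles radians, or pass `n` and `r` directly.
#' @param n,r sample size and mean resultant length (alternative input).
#' @return list: `r`, `z`, `p`, `n`.
#' @export
rayleigh_test <- function(angles = NULL, n = NULL, r = NULL) {
  if (!is.null(angles)) {
    angles <- angles[is.finite(angles)]
    n <- length(angles)
    r <- Mod(mean(exp(1i * angles)))
  }
  stopifnot(n >= 1, r >= 0)
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  list(r = r, z = z, p = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Steady-state analysis for one condition against baseline
#'
#' Runs the complete steady-state quantification for one stimulation
#' condition: per-trial multitaper PSD, fold-change in power at the
#' stimulation frequency with trial-permutation significance, PLV with
#' Rayleigh test, and the two-cycle evoked average.
#'
#' @param stim,baseline filtered `trial_tensor`s with equal trial counts
#'   (use [balance_trials()]).
#' @param f_stim stimulation frequency, Hz.
#' @param n_perm permutation count (default 10000).
#' @param seed RNG seed for the permutation test.
#' @param compute_plv,compute_evoked toggles for the slower stages.
#' @return data.frame, one row per channel: `contact_id`, `fold_change`,
#'   `p_perm`, `plv`, `rayleigh_p`, `n_trials`; the evoked average is
#'   attached as attribute `"evoked"`.
#' @export
steady_state_condition <- function(stim, baseline, f_stim, n_perm = 10000,
                                   seed = NULL, compute_plv = TRUE,
                                   compute_evoked = FALSE) {
  stopifnot(dim(stim$data)[1] == dim(baseline$data)[1])
  if (!is.null(seed)) withr::local_seed(seed)
  ps <- multitaper_psd(stim)
  pb <- multitaper_psd(baseline)
  pow_s <- power_at(ps, f_stim)
  pow_b <- power_at(pb, f_stim)
  n_ch <- ncol(pow_s)
  fc <- p <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    r <- fold_change(pow_s[, ch], pow_b[, ch], n_perm = n_perm)
    fc[ch] <- r$fold_change
    p[ch] <- r$p_perm
  }
  res <- data.frame(contact_id = colnames(pow_s), condition = stim$condition,
                    fold_change = fc, p_perm = p,
                    plv = NA_real_, rayleigh_p = NA_real_,
                    n_trials = dim(stim$data)[1],
                    stringsAsFactors = FALSE)
  if (compute_plv) {
    pl <- phase_locking(stim, f_stim)
    res$plv <- pl$plv
    res$rayleigh_p <- pl$rayleigh_p
  }
  if (compute_evoked) {
    attr(res, "evoked") <- evoked_two_cycle(stim, f_stim)
  }
  res
}
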