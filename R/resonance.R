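#' The 26 stimulation frequencies of the wide-range flicker paradigm
#'
#' Spans 5.5-80 Hz in roughly 3 Hz steps; note the gap between 57 and
#' 63 Hz (no condition at the 60 Hz mains frequency).
#'
#' @return numeric vector of 26 frequencies, Hz.
#' @export
flicker_frequencies <- function() {
  c(5.5, 8, 11, 14, 17, 20, 23, 26, 29, 32, 35, 38, 40, 42, 45, 48, 51,
    54, 57, 63, 66, 69, 72, 75, 78, 80)
}

#' Parameterize a baseline power spectrum into aperiodic and peak parts
#'
#' Decomposes the mean baseline PSD over 2-100 Hz into a 1/f aperiodic
#' component (offset and exponent, fit in log10-log10 space) plus up to
#' `max_n_peaks` Gaussian oscillation peaks, following the standard
#' spectral-parameterization scheme: a robust aperiodic fit (refit on
#' the low-residual points so peaks do not bias it), iterative peak
#' extraction from the flattened spectrum, a joint Gaussian refit, and a
#' final aperiodic refit on the peak-removed spectrum. Detection
#' parameters default to the settings used for the flicker analyses:
#' at most 5 peaks, peak widths 2-10 Hz, minimum peak height 0.6
#' (log10 power over the aperiodic fit), range 2-100 Hz. Each reported
#' peak carries `fold_vs_aperiodic`: the fold-change in (linear) power
#' of the modeled PSD at the peak center relative to the aperiodic fit.
#'
#' @param freq frequency grid, Hz.
#' @param psd mean baseline PSD (linear power) on `freq`.
#' @param max_n_peaks maximum number of peaks (default 5).
#' @param peak_width_limits width limits in Hz (default `c(2, 10)`;
#'   width = 2 Gaussian SDs).
#' @param min_peak_height minimum peak height, log10 power units
#'   (default 0.6).
#' @param freq_range fitted range, Hz (default `c(2, 100)`).
#' @return list of class `psd_param`: `aperiodic` (offset, exponent),
#'   `peaks` (data.frame: center, height, width, fold_vs_aperiodic),
#'   `freq`, `model` and `aperiodic_fit` (log10 power), `error` (RMSE).
#'   A failed fit returns zero peaks and a diagnostic message.
#' @export
detect_endogenous <- function(freq, psd, max_n_peaks = 5,
                              peak_width_limits = c(2, 10),
                              min_peak_height = 0.6,
                              freq_range = c(2, 100)) {
  keep <- freq >= freq_range[1] & freq <= freq_range[2] & freq > 0
  f <- freq[keep]
  lp <- log10(pmax(psd[keep], .Machine$double.xmin))
  sd_lim <- peak_width_limits / 2
  ap <- robust_aperiodic_fit(f, lp)
  flat <- lp - ap_eval(ap, f)
  peaks <- list()
  work <- flat
  for (i in seq_len(max_n_peaks)) {
    j <- which.max(work)
    height <- work[j]
    if (height < max(min_peak_height, 2 * stats::sd(work))) break
    center <- f[j]
    half <- height / 2
    ri <- j; while (ri < length(f) && work[ri] > half) ri <- ri + 1
    li <- j; while (li > 1 && work[li] > half) li <- li - 1
    fwhm <- f[ri] - f[li]
    sdg <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    peaks[[length(peaks) + 1]] <- c(center, height, sdg)
    work <- work - height * exp(-(f - center)^2 / (2 * sdg^2))
  }
  if (length(peaks)) {
    guess <- do.call(rbind, peaks)
    refit <- tryCatch(
      gaussian_refit(f, flat, guess, sd_lim, freq_range),
      error = function(e) {
        message("peak refit failed (", conditionMessage(e),
                "); keeping iterative estimates")
        guess
      })
    # drop peaks that fell below the height threshold in the joint fit
    refit <- refit[refit[, 2] >= min_peak_height, , drop = FALSE]
    peaks <- refit
  } else {
    peaks <- matrix(numeric(0), 0, 3)
  }
  peak_lp <- gauss_sum(f, peaks)
  ap <- fit_aperiodic(f, lp - peak_lp)
  model <- ap_eval(ap, f) + peak_lp
  pk_df <- data.frame(center = peaks[, 1], height = peaks[, 2],
                      width = 2 * peaks[, 3])
  pk_df$fold_vs_aperiodic <- if (nrow(pk_df)) {
    10^gauss_sum(pk_df$center, peaks) - 1
  } else numeric(0)
  structure(list(aperiodic = ap, peaks = pk_df, freq = f, model = model,
                 aperiodic_fit = ap_eval(ap, f),
                 error = sqrt(mean((lp - model)^2))),
            class = "psd_param")
}

ap_eval <- function(ap, f) ap[["offset"]] - ap[["exponent"]] * log10(f)

fit_aperiodic <- function(f, lp) {
  co <- stats::coef(stats::lm(lp ~ log10(f)))
  c(offset = unname(co[1]), exponent = unname(-co[2]))
}

# refit on low-residual points so oscillation peaks do not bias the fit
robust_aperiodic_fit <- function(f, lp) {
  ap <- fit_aperiodic(f, lp)
  resid <- lp - ap_eval(ap, f)
  resid[resid < 0] <- 0
  thr <- stats::quantile(resid, 0.025)
  mask <- resid <= thr
  if (sum(mask) >= 5) ap <- fit_aperiodic(f[mask], lp[mask])
  ap
}

gauss_sum <- function(f, peaks) {
  out <- numeric(length(f))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks[i, 2] *
      exp(-(f - peaks[i, 1])^2 / (2 * peaks[i, 3]^2))
  }
  out
}

gaussian_refit <- function(f, flat, guess, sd_lim, freq_range) {
  n_pk <- nrow(guess)
  par0 <- as.vector(t(guess))
  lower <- as.vector(t(cbind(pmax(guess[, 1] - 2 * guess[, 3], freq_range[1]),
                             0, sd_lim[1])))
  upper <- as.vector(t(cbind(pmin(guess[, 1] + 2 * guess[, 3], freq_range[2]),
                             Inf, sd_lim[2])))
  fn <- function(p) {
    pk <- matrix(p, ncol = 3, byrow = TRUE)
    flat - gauss_sum(f, pk)
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  matrix(fit$par, ncol = 3, byrow = TRUE)
}

#' Frequency-preference profile of each contact across the 26-frequency
#' paradigm
#'
#' Runs the steady-state quantification (fold-change with permutation
#' significance, and optionally PLV with Rayleigh test) for every
#' stimulation frequency of the wide-range paradigm, then tabulates per
#' channel: the number of frequencies with significant modulation, the
#' top frequency (argmax fold-change among significant frequencies;
#' ties broken toward the lower frequency), and min-max normalized
#' response rows for heatmap display.
#'
#' @param tensors named list of filtered `trial_tensor`s; names are
#'   condition labels. Must include the baseline condition.
#' @param baseline name of the baseline condition
#'   (default "none\@baseline").
#' @param frequencies stimulation frequencies to profile (default
#'   [flicker_frequencies()]).
#' @param n_perm permutations for the fold-change test.
#' @param seed RNG seed.
#' @param alpha significance level (default 0.05).
#' @param compute_plv also compute PLV per frequency (default TRUE).
#' @return list of class `frequency_profile`: `table` (long data.frame
#'   channel x frequency), `summary` (per channel: `n_significant_power`,
#'   `n_significant_plv`, `top_freq_power`, `top_freq_plv`),
#'   `norm_power`, `norm_plv` (channels x 26 min-max normalized
#'   matrices), `frequencies`, `alpha`.
#' @export
frequency_profile <- function(tensors, baseline = "none@baseline",
                              frequencies = flicker_frequencies(),
                              n_perm = 10000, seed = NULL, alpha = 0.05,
                              compute_plv = TRUE) {
  stopifnot(baseline %in% names(tensors))
  if (!is.null(seed)) withr::local_seed(seed)
  bl <- tensors[[baseline]]
  rows <- list()
  for (f in frequencies) {
    cond <- grep(paste0("@", f, "$"), names(tensors), value = TRUE)
    if (!length(cond)) stop("no condition found for ", f, " Hz")
    res <- steady_state_condition(tensors[[cond[1]]], bl, f,
                                  n_perm = n_perm,
                                  compute_plv = compute_plv)
    res$frequency <- f
    rows[[length(rows) + 1]] <- res
  }
  tab <- do.call(rbind, rows)
  chans <- unique(tab$contact_id)
  nf <- length(frequencies)
  summ <- data.frame(contact_id = chans,
                     n_significant_power = NA_integer_,
                     n_significant_plv = NA_integer_,
                     top_freq_power = NA_real_, top_freq_plv = NA_real_,
                     stringsAsFactors = FALSE)
  norm_pow <- norm_plv <- matrix(NA_real_, length(chans), nf,
                                 dimnames = list(chans, frequencies))
  minmax <- function(v) {
    if (diff(range(v)) == 0) rep(0, length(v))
    else (v - min(v)) / diff(range(v))
  }
  for (i in seq_along(chans)) {
    sub <- tab[tab$contact_id == chans[i], ]
    sub <- sub[match(frequencies, sub$frequency), ]
    sig_p <- sub$p_perm < alpha
    summ$n_significant_power[i] <- sum(sig_p)
    if (any(sig_p)) {
      fc <- sub$fold_change
      best <- max(fc[sig_p])
      cand <- frequencies[sig_p & fc >= best - 1e-12]
      if (length(cand) > 1) {
        message("contact ", chans[i], ": tied top frequency, using ",
                min(cand), " Hz")
      }
      summ$top_freq_power[i] <- min(cand)
    }
    norm_pow[i, ] <- minmax(sub$fold_change)
    if (compute_plv) {
      sig_v <- sub$rayleigh_p < alpha
      summ$n_significant_plv[i] <- sum(sig_v)
      if (any(sig_v)) {
        best <- max(sub$plv[sig_v])
        summ$top_freq_plv[i] <- min(frequencies[sig_v &
                                                  sub$plv >= best - 1e-12])
      }
      norm_plv[i, ] <- minmax(sub$plv)
    }
  }
  structure(list(table = tab, summary = summ, norm_power = norm_pow,
                 norm_plv = norm_plv, frequencies = frequencies,
                 alpha = alpha),
            class = "frequency_profile")
}

#' Match a contact's top stimulation frequency to its endogenous
#' oscillations
#'
#' Entrainment-style comparison: a contact is eligible if it shows
#' significant power modulation at more than `min_significant`
#' stimulation frequencies and has at least one detected endogenous
#' peak; it is "matched" if its top stimulation frequency lies within
#' `tol` of the nearest endogenous peak center.
#'
#' @param top_freq top stimulation frequency, Hz (from
#'   [frequency_profile()]).
#' @param n_significant number of significantly modulated frequencies.
#' @param peak_centers endogenous peak centers, Hz (from
#'   [detect_endogenous()]).
#' @param tol match tolerance, Hz (default 5).
#' @param min_significant eligibility threshold (default 6, i.e.
#'   "more than 6 of the 26 frequencies").
#' @return list: `eligible`, `matched`, `top_freq`, `nearest_endog`
#'   (NA when ineligible/absent).
#' @export
entrainment_match <- function(top_freq, n_significant, peak_centers,
                              tol = 5, min_significant = 6) {
  eligible <- !is.na(top_freq) && n_significant > min_significant &&
    length(peak_centers) >= 1
  if (!eligible) {
    return(list(eligible = FALSE, matched = NA, top_freq = top_freq,
                nearest_endog = NA_real_))
  }
  nearest <- peak_centers[which.min(abs(peak_centers - top_freq))]
  list(eligible = TRUE, matched = abs(top_freq - nearest) <= tol,
       top_freq = top_freq, nearest_endog = nearest)
}
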