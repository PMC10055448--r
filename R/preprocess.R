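#' Laplacian re-referencing of depth-electrode recordings
#'
#' Re-references each contact against its neighbors on the same probe to
#' localize signal sources and reject volume-conducted and common-mode
#' activity. Interior contacts get the Laplacian montage,
#' `x_i - (x_{i-1} + x_{i+1}) / 2`; contacts at probe extremities get
#' bipolar referencing (end contact minus its single neighbor). When a
#' neighbor has been excluded (noisy, extra-parenchymal, ...), the
#' nearest non-excluded contact on the same side of the same probe is
#' used instead. A contact with no usable neighbor on either side — in
#' particular any single-contact probe — is marked excluded, with a
#' warning.
#'
#' @param rec a [new_recording()] object.
#' @return a `flicker_recording` with re-referenced samples; newly
#'   isolated contacts have `excluded = TRUE`.
#' @export
rereference_laplacian <- function(rec) {
  stopifnot(inherits(rec, "flicker_recording"))
  ch <- rec$channels
  out <- rec$samples
  newly_excluded <- character(0)
  for (probe in unique(ch$probe_id)) {
    rows <- which(ch$probe_id == probe)
    rows <- rows[order(ch$probe_index[rows])]
    usable <- rows[!ch$excluded[rows]]
    for (pos in seq_along(rows)) {
      i <- rows[pos]
      if (ch$excluded[i]) next
      below <- usable[usable %in% rows[seq_len(pos - 1)]]
      above <- usable[usable %in% rows[-seq_len(pos)]]
      lo <- if (length(below)) below[length(below)] else NA_integer_
      hi <- if (length(above)) above[1] else NA_integer_
      if (is.na(lo) && is.na(hi)) {
        newly_excluded <- c(newly_excluded, ch$contact_id[i])
        ch$excluded[i] <- TRUE
      } else if (is.na(lo)) {
        out[i, ] <- rec$samples[i, ] - rec$samples[hi, ]
      } else if (is.na(hi)) {
        out[i, ] <- rec$samples[i, ] - rec$samples[lo, ]
      } else {
        out[i, ] <- rec$samples[i, ] -
          (rec$samples[lo, ] + rec$samples[hi, ]) / 2
      }
    }
  }
  if (length(newly_excluded)) {
    warning("contacts with no usable neighbor excluded: ",
            paste(newly_excluded, collapse = ", "))
  }
  new_recording(out, rec$fs, ch)
}

#' Segment a recording into per-condition trial tensors
#'
#' Cuts the recording into one segment per trial, padded symmetrically
#' on both sides to absorb subsequent filter edge artifacts (10 s trials
#' with a 1 s pad give the 12 s working segments). Excluded channels are
#' dropped here and never reappear downstream.
#'
#' @param rec a `flicker_recording`.
#' @param trials a [trial_table()].
#' @param pad pad on each side, seconds (default 1).
#' @return named list of `trial_tensor`, one per condition label.
#' @export
segment_trials <- function(rec, trials, pad = 1) {
  stopifnot(inherits(rec, "flicker_recording"), pad >= 0)
  fs <- rec$fs
  n_time <- ncol(rec$samples)
  keep <- !rec$channels$excluded
  conds <- condition_of(trials)
  out <- list()
  for (cond in unique(conds)) {
    rows <- which(conds == cond)
    dur <- unique(round(trials$duration_s[rows] * fs))
    if (length(dur) != 1) {
      stop("trials of condition ", cond, " have unequal durations")
    }
    seg_len <- dur + 2L * round(pad * fs)
    onset_samples <- round(trials$onset_s[rows] * fs)  # 0-based
    starts <- onset_samples - round(pad * fs)
    bad <- which(starts < 0 | starts + seg_len > n_time)
    if (length(bad)) {
      stop("trial ", trials$trial_id[rows[bad[1]]],
           " (", cond, ") exceeds recording bounds")
    }
    dat <- array(NA_real_, c(length(rows), sum(keep), seg_len))
    for (j in seq_along(rows)) {
      dat[j, , ] <- rec$samples[keep, (starts[j] + 1):(starts[j] + seg_len),
                                drop = FALSE]
    }
    out[[cond]] <- new_trial_tensor(
      dat, fs, cond, pad, onset_samples,
      trials$trial_id[rows], rec$channels$contact_id[keep])
  }
  out
}

#' Band-pass filter flicker segments and remove per-segment baseline
#'
#' Applies a zero-phase 2-300 Hz Butterworth band-pass (order-4 high-
#' and low-pass cascade, forward-backward), subtracts each trial's and
#' channel's mean over the whole padded segment, then trims the pads so
#' the output covers exactly the stimulation window. If the sampling
#' rate cannot support the 300 Hz edge the upper cutoff is clipped to
#' `0.45 * fs` with a warning.
#'
#' @param seg a `trial_tensor` (padded), or list of them.
#' @param band numeric length-2, Hz (default `c(2, 300)`).
#' @param order one-way Butterworth order per edge (default 4).
#' @return `trial_tensor` (or list) with `pad = 0`, filtered and
#'   baseline-corrected.
#' @export
filter_flicker <- function(seg, band = c(2, 300), order = 4) {
  if (is.list(seg) && !inherits(seg, "trial_tensor")) {
    return(lapply(seg, filter_flicker, band = band, order = order))
  }
  stopifnot(inherits(seg, "trial_tensor"))
  fs <- seg$fs
  hi <- band[2]
  if (fs <= 2 * band[2]) {
    hi <- 0.45 * fs
    warning(sprintf("fs = %g cannot support the %g Hz edge; clipped to %g Hz",
                    fs, band[2], hi))
  }
  hp <- butter_sos(order, band[1], fs, "high")
  lp <- butter_sos(order, hi, fs, "low")
  d <- dim(seg$data)
  pad_n <- round(seg$pad * fs)
  keep_idx <- (pad_n + 1):(d[3] - pad_n)
  out <- array(NA_real_, c(d[1], d[2], length(keep_idx)))
  for (tr in seq_len(d[1])) {
    x <- matrix(seg$data[tr, , ], nrow = d[2])
    x <- filtfilt_sos(x, list(hp, lp))
    x <- x - rowMeans(x)  # baseline over the full padded segment
    out[tr, , ] <- x[, keep_idx, drop = FALSE]
  }
  new_trial_tensor(out, fs, seg$condition, 0, seg$onset_samples,
                   seg$trial_ids, dimnames(seg$data)[[2]])
}

#' Equalize trial counts across conditions
#'
#' Randomly subsamples (without replacement) every condition down to the
#' minimum trial count, so that condition means and their permutation
#' nulls are computed from equal numbers of trials. The selection is
#' seeded and the chosen indices are attached for provenance.
#'
#' @param tensors named list of `trial_tensor`.
#' @param seed integer seed for the subsampling.
#' @return list of `trial_tensor` with equal trial counts; each carries
#'   attribute `"selected"` with the retained original trial positions.
#' @export
balance_trials <- function(tensors, seed = 1L) {
  stopifnot(length(tensors) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- vapply(tensors, function(tt) dim(tt$data)[1], integer(1))
  n_min <- min(counts)
  lapply(tensors, function(tt) {
    n <- dim(tt$data)[1]
    sel <- if (n > n_min) sort(sample.int(n, n_min)) else seq_len(n)
    tt$data <- tt$data[sel, , , drop = FALSE]
    tt$onset_samples <- tt$onset_samples[sel]
    tt$trial_ids <- tt$trial_ids[sel]
    attr(tt, "selected") <- sel
    tt
  })
}
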