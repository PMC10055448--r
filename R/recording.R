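#' Multichannel LFP recording container
#'
#' A `flicker_recording` bundles a channels-by-time sample matrix
#' (microvolts), its sampling rate, and a channel table describing how
#' contacts are organized along depth electrodes (probes). Contact order
#' within a probe is deep-to-superficial, given by `probe_index`.
#' Excluded channels stay in the matrix (so indexing is stable) but are
#' never emitted in downstream results.
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param fs sampling rate, samples/second.
#' @param channels data.frame with columns `contact_id`, `probe_id`,
#'   `probe_index` (1-based position along the probe, deep to
#'   superficial) and `excluded` (logical). Optional columns (anatomical
#'   label, x/y/z mm coordinates) are carried through untouched.
#' @return object of class `flicker_recording`.
#' @export
new_recording <- function(samples, fs, channels) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1, fs > 0)
  stopifnot(is.data.frame(channels),
            all(c("contact_id", "probe_id", "probe_index") %in%
                  names(channels)),
            nrow(channels) == nrow(samples))
  if (is.null(channels$excluded)) channels$excluded <- FALSE
  channels$contact_id <- as.character(channels$contact_id)
  channels$excluded <- as.logical(channels$excluded)
  if (anyDuplicated(channels$contact_id)) {
    stop("contact identifiers must be unique")
  }
  dup <- duplicated(channels[, c("probe_id", "probe_index")])
  if (any(dup)) stop("duplicated probe position in channel table")
  rownames(samples) <- channels$contact_id
  structure(list(samples = samples, fs = fs, channels = channels),
            class = "flicker_recording")
}

#' @export
print.flicker_recording <- function(x, ...) {
  cat(sprintf(
    "<flicker_recording> %d channels (%d excluded) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), sum(x$channels$excluded), ncol(x$samples), x$fs,
    ncol(x$samples) / x$fs))
  invisible(x)
}

#' Trial/event table constructor and validator
#'
#' Trials are rows of (modality, frequency-or-tag, onset, duration).
#' `frequency` is stored as character: a number in Hz for periodic
#' flicker, or the tags `"random"` (non-periodic pulse train) and
#' `"baseline"` (no stimulation). Onsets are seconds from recording
#' start; windows are half-open `[onset, onset + duration)`.
#'
#' @param modality one of "visual", "audiovisual", "auditory", "none".
#' @param frequency numeric Hz or "random"/"baseline" per trial.
#' @param onset_s,duration_s seconds.
#' @param trial_id optional identifiers (default sequential).
#' @return data.frame of class `trial_table`, ordered by onset.
#' @export
trial_table <- function(modality, frequency, onset_s, duration_s,
                        trial_id = NULL) {
  n <- length(onset_s)
  modality <- rep_len(as.character(modality), n)
  frequency <- rep_len(as.character(frequency), n)
  duration_s <- rep_len(as.numeric(duration_s), n)
  if (is.null(trial_id)) trial_id <- seq_len(n)
  bad_mod <- setdiff(modality, c("visual", "audiovisual", "auditory", "none"))
  if (length(bad_mod)) stop("unknown modality: ", paste(bad_mod, collapse = ", "))
  stopifnot(all(duration_s > 0), all(onset_s >= 0))
  tt <- data.frame(trial_id = trial_id, modality = modality,
                   frequency = frequency, onset_s = as.numeric(onset_s),
                   duration_s = duration_s, stringsAsFactors = FALSE)
  tt <- tt[order(tt$onset_s), , drop = FALSE]
  if (any(diff(tt$onset_s) <= 0)) stop("trial onsets must be strictly increasing")
  ends <- tt$onset_s + tt$duration_s
  if (any(ends[-nrow(tt)] > tt$onset_s[-1] + 1e-9)) {
    stop("trials must not overlap")
  }
  rownames(tt) <- NULL
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Condition label of each trial ("modality@frequency")
#' @param trials a `trial_table`.
#' @return character vector, e.g. `"visual@40"`, `"none@baseline"`.
#' @export
condition_of <- function(trials) {
  paste0(trials$modality, "@", trials$frequency)
}

#' Numeric stimulation frequency of a condition label (NA for tags)
#' @param condition condition label(s) as produced by [condition_of()].
#' @return numeric Hz, NA for "random"/"baseline".
#' @export
condition_frequency <- function(condition) {
  suppressWarnings(as.numeric(sub("^.*@", "", condition)))
}

#' Trial tensor: trials x channels x time for one condition
#' @keywords internal
new_trial_tensor <- function(data, fs, condition, pad, onset_samples,
                             trial_ids, contact_ids) {
  stopifnot(length(dim(data)) == 3)
  dimnames(data) <- list(NULL, contact_ids, NULL)
  structure(list(data = data, fs = fs, condition = condition, pad = pad,
                 onset_samples = onset_samples, trial_ids = trial_ids),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_tensor> %s: %d trials x %d channels x %d samples @ %g Hz (pad %g s)\n",
              x$condition, d[1], d[2], d[3], x$fs, x$pad))
  invisible(x)
}
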