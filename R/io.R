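#' File interfaces
#'
#' Recordings travel as a two-file bundle: an RDS container holding the
#' channels-by-time sample matrix and sampling rate, next to a TSV
#' channel table (`contact_id`, `probe_id`, `probe_index`, `excluded`,
#' plus any annotation columns such as `anatomical_label` or `x/y/z`
#' mm). Trial tables, event streams and result tables are plain TSV.
#'
#' @param rec a `flicker_recording`.
#' @param path basename; writes `<path>.rds` and `<path>_channels.tsv`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `flicker_recording`.
#' @name recording_io
NULL

#' @rdname recording_io
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "flicker_recording"))
  saveRDS(list(samples = rec$samples, fs = rec$fs),
          paste0(path, ".rds"))
  utils::write.table(rec$channels, paste0(path, "_channels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording <- function(path) {
  core <- readRDS(paste0(path, ".rds"))
  channels <- utils::read.delim(paste0(path, "_channels.tsv"),
                                stringsAsFactors = FALSE)
  new_recording(core$samples, core$fs, channels)
}

#' Read/write trial tables as TSV
#'
#' Columns: `trial_id`, `modality`, `frequency` (Hz or the tags
#' "random"/"baseline"), `onset_s`, `duration_s`.
#'
#' @param trials a [trial_table()].
#' @param path TSV path.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
write_trials <- function(trials, path) {
  utils::write.table(as.data.frame(trials), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_trials <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(frequency = "character"))
  trial_table(d$modality, d$frequency, d$onset_s, d$duration_s,
              trial_id = d$trial_id)
}

#' Read/write IED event streams as TSV
#'
#' Columns: `t_s` (seconds), `channel_ids` (comma-joined contact ids).
#'
#' @param events data.frame with `t_s` and a `channels` list column.
#' @param path TSV path.
#' @name event_io
NULL

#' @rdname event_io
#' @export
write_events <- function(events, path) {
  out <- data.frame(t_s = events$t_s,
                    channel_ids = vapply(events$channels, paste,
                                         character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname event_io
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(t_s = d$t_s, channels = I(strsplit(d$channel_ids, ",")))
}

#' Write a ground-truth sidecar as YAML
#' @param gt a [ground_truth()].
#' @param path YAML path.
#' @export
write_ground_truth <- function(gt, path) {
  yaml::write_yaml(unclass(gt), path)
  invisible(path)
}
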