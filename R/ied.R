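#' Merge detector spikes into IEDs and reject wide noise events
#'
#' Detector output often fragments one interictal discharge into several
#' per-channel spikes. Events whose successive times differ by at most
#' `max_gap` are chain-merged into one IED (a polyspike): the merged
#' event takes the first constituent's time and the union of the channel
#' sets. Merged IEDs spanning more than `max_channels` channels are
#' treated as noise and removed.
#'
#' @param events data.frame with `t_s` (seconds) and `channels` (list
#'   column of channel-id vectors, or a comma-joined character column).
#' @param max_gap merge window, seconds (default 0.1).
#' @param max_channels channel-count rejection threshold (default 11;
#'   events on more than 11 channels are dropped).
#' @return data.frame of merged IEDs, same layout, sorted by time.
#' @export
merge_and_filter <- function(events, max_gap = 0.1, max_channels = 11) {
  if (nrow(events) == 0) return(events)
  ch <- events$channels
  if (is.character(ch)) ch <- strsplit(ch, ",[ ]*")
  ord <- order(events$t_s)
  t <- events$t_s[ord]
  ch <- ch[ord]
  grp <- cumsum(c(1, as.integer(diff(t) > max_gap + 1e-12)))
  t_out <- tapply(t, grp, function(v) v[1])
  ch_out <- lapply(split(ch, grp), function(l) unique(unlist(l)))
  keep <- lengths(ch_out) <= max_channels
  data.frame(t_s = as.numeric(t_out[keep]),
             channels = I(unname(ch_out[keep])))
}

#' Proportion of IEDs occurring during stimulation, per session
#'
#' For every stimulation trial paired with its immediately following
#' baseline trial of equal duration, the per-trial proportion is
#' `n_stim / (n_stim + n_baseline)`; 20 s trial pairs with no IEDs are
#' omitted. Proportions are averaged within each stimulation condition,
#' then across conditions, yielding one value per session in [0, 1]
#' (0.5 = no difference between stimulation and baseline).
#'
#' @param events merged IED events ([merge_and_filter()] output) or any
#'   data.frame with `t_s`.
#' @param trials a [trial_table()] containing the stimulation trials and
#'   their following baseline trials.
#' @return list: `session` (scalar proportion, NA if no trial pair
#'   retained), `by_condition` (data.frame: condition, proportion,
#'   n_trials_used), `by_trial`.
#' @export
stim_proportion <- function(events, trials) {
  conds <- condition_of(trials)
  is_stim <- trials$modality != "none" & trials$frequency != "baseline"
  stim_rows <- which(is_stim)
  per_trial <- list()
  for (r in stim_rows) {
    o <- trials$onset_s[r]
    dur <- trials$duration_s[r]
    b <- which(!is_stim & abs(trials$onset_s - (o + dur)) < 1e-6)
    if (!length(b)) {
      stop("stimulation trial ", trials$trial_id[r],
           " has no immediately following baseline trial")
    }
    b <- b[1]
    if (abs(trials$duration_s[b] - dur) > 1e-9) {
      stop("baseline trial ", trials$trial_id[b],
           " does not match the stimulation duration")
    }
    n_s <- sum(events$t_s >= o & events$t_s < o + dur)
    n_b <- sum(events$t_s >= trials$onset_s[b] &
                 events$t_s < trials$onset_s[b] + dur)
    if (n_s + n_b == 0) next
    per_trial[[length(per_trial) + 1]] <-
      data.frame(condition = conds[r], trial_id = trials$trial_id[r],
                 n_stim = n_s, n_base = n_b,
                 proportion = n_s / (n_s + n_b),
                 stringsAsFactors = FALSE)
  }
  if (!length(per_trial)) {
    return(list(session = NA_real_,
                by_condition = data.frame(condition = character(0),
                                          proportion = numeric(0),
                                          n_trials_used = integer(0)),
                by_trial = data.frame()))
  }
  bt <- do.call(rbind, per_trial)
  bc <- aggregate(proportion ~ condition, bt, mean)
  bc$n_trials_used <- as.integer(table(bt$condition)[bc$condition])
  list(session = mean(bc$proportion), by_condition = bc, by_trial = bt)
}

#' Group-level test of an IED decrease during stimulation
#'
#' One-sample, one-sided t-test of the per-session stimulation
#' proportions against 0.5 (alternative: mean < 0.5, i.e. fewer IEDs
#' during stimulation). Sessions are treated as independent. A
#' zero-variance input (all sessions identical) cannot be tested; it is
#' reported with p = 1 and a warning.
#'
#' @param session_values per-session proportions in [0, 1].
#' @return list: `mean_deviation` (mean of values - 0.5), `t`, `df`,
#'   `p_one_sided`.
#' @export
group_test <- function(session_values) {
  stopifnot(length(session_values) >= 2,
            all(session_values >= 0 & session_values <= 1))
  dev <- mean(session_values) - 0.5
  if (stats::sd(session_values) == 0) {
    warning("zero variance across sessions; t-test undefined, p = 1")
    return(list(mean_deviation = dev, t = NA_real_,
                df = length(session_values) - 1L, p_one_sided = 1))
  }
  tt <- stats::t.test(session_values, mu = 0.5, alternative = "less")
  list(mean_deviation = dev, t = unname(tt$statistic),
       df = unname(tt$parameter), p_one_sided = tt$p.value)
}
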