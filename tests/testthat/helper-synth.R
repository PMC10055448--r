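# Shared fixtures, built in code at test time.

# von Mises sampler (Best & Fisher rejection scheme) — independent of
# the package's spike generator, for circular-statistics oracles.
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out
}

# Generate, segment, filter and balance a small synthetic session.
quick_session <- function(gt, conditions, n_each = 8, fs = 500,
                          seed = 1L, duration = 10) {
  trials <- make_trial_schedule(conditions, n_each = n_each,
                                duration = duration, seed = seed)
  ses <- make_lfp_session(gt, trials, fs = fs, seed = seed)
  tensors <- segment_trials(ses$rec, ses$trials, pad = 1)
  tensors <- suppressWarnings(filter_flicker(tensors))
  tensors <- balance_trials(tensors, seed = seed)
  list(session = ses, tensors = tensors)
}

# Trial tensor with one channel built directly from a trials x time
# matrix (bypasses segmentation, for constructed oracles).
tensor_from_matrix <- function(m, fs, condition = "visual@40") {
  arr <- array(m, c(nrow(m), 1, ncol(m)))
  flickerlfp:::new_trial_tensor(arr, fs, condition, 0,
                                onset_samples = rep(0L, nrow(m)),
                                trial_ids = seq_len(nrow(m)),
                                contact_ids = "c01")
}

# Brute-force IED chain-merging oracle: O(n^2) interval clustering.
merge_oracle <- function(times, channels, max_gap = 0.1,
                         max_channels = 11) {
  ord <- order(times)
  times <- times[ord]; channels <- channels[ord]
  groups <- list(); cur <- c(1)
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] <= max_gap + 1e-12) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- c(i)
    }
  }
  groups[[length(groups) + 1]] <- cur
  t_out <- vapply(groups, function(g) times[g[1]], numeric(1))
  ch_out <- lapply(groups, function(g) unique(unlist(channels[g])))
  keep <- lengths(ch_out) <= max_channels
  list(t_s = t_out[keep], channels = ch_out[keep])
}

# Brute-force anatomical assignment oracle: enumerate every voxel in
# the volume, filter by distance and label, sum 1/r weights.
assign_oracle <- function(xyz, grid, radius = 5) {
  dims <- dim(grid$data)
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  r <- sqrt(rowSums(sweep(world, 2, xyz)^2))
  lab <- grid$data[ijk + 1]
  keep <- r <= radius & lab > 0 & !(lab %in% grid$excluded_labels)
  if (!any(keep)) return(NA_integer_)
  scores <- tapply(pmin(1, 1 / r[keep]), lab[keep], sum)
  min(as.integer(names(scores)[scores >= max(scores) - 1e-12]))
}

random_label_grid <- function(n = 12, n_labels = 4, wm = 99L,
                              voxel = 1.5) {
  data <- array(sample(c(0:n_labels, wm), n^3, replace = TRUE),
                c(n, n, n))
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- stats::runif(3, -2, 2)
  label_grid(data, affine, excluded_labels = wm)
}
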