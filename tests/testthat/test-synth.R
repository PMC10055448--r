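test_that("stimulus waveforms have the stated pulse structure", {
  st <- make_stimulus("visual", 40, 1, 10000)
  expect_length(st$onsets, 40)
  expect_equal(mean(st$envelope), 0.5)           # 50% duty cycle
  # each pulse is 12.5 ms on: 125 samples at 10 kHz
  runs <- rle(st$envelope)
  expect_true(all(runs$lengths[runs$values == 1] == 125))

  # random trains: mean pulse period 25 ms (12.5 ms on + U(0,25) ms gap)
  st_r <- make_stimulus("visual", "random", 200, 1000, seed = 4)
  expect_equal(mean(diff(st_r$onsets)), 0.025, tolerance = 0.02)
  expect_equal(st_r$frequency, "random")
})

test_that("sessions are bit-reproducible under a fixed seed", {
  gt <- ground_truth(n_channels = 2, fold_change = 1)
  tr <- make_trial_schedule("visual@40", n_each = 2, seed = 9)
  s1 <- make_lfp_session(gt, tr, fs = 250, seed = 42)
  s2 <- make_lfp_session(gt, tr, fs = 250, seed = 42)
  expect_identical(s1$rec$samples, s2$rec$samples)
  sp1 <- make_spikes(gt, tr, seed = 7)
  sp2 <- make_spikes(gt, tr, seed = 7)
  expect_identical(sp1, sp2)
  ie1 <- make_ieds(gt, tr, seed = 3)
  ie2 <- make_ieds(gt, tr, seed = 3)
  expect_identical(ie1, ie2)
})

test_that("baseline noise follows the target aperiodic exponent", {
  gt <- ground_truth(aperiodic_offset = 1, aperiodic_exponent = 1.6)
  tr <- trial_table("none", "baseline", 1, 600)  # 10-minute baseline
  ses <- make_lfp_session(gt, tr, fs = 250, seed = 8)
  # Welch-style mean PSD over 10 s windows
  x <- ses$rec$samples[1, 251:(600 * 250)]
  segs <- matrix(x[1:(59 * 2500)], nrow = 59, byrow = TRUE)
  p <- multitaper_psd(segs, 250, fmin = 2, fmax = 90)
  fit <- lm(log10(colMeans(p$psd)) ~ log10(p$freq))
  expect_equal(unname(-coef(fit)[2]), 1.6, tolerance = 0.1)
})

test_that("a delta-like kernel in superposition mode reproduces the
           pulse train spectrum", {
  fs <- 500
  gt <- ground_truth(aperiodic_offset = -2, response_mode = "linear_superposition",
                     kernel = list(amp = 50, freq = 125, decay = 0.002))
  tr <- make_trial_schedule("visual@40", n_each = 1, seed = 1)
  ses <- make_lfp_session(gt, tr, fs = fs, seed = 2, return_clean = TRUE)
  i0 <- round(tr$onset_s[1] * fs)
  clean <- ses$clean[1, (i0 + 1):(i0 + 10 * fs)]
  # Fourier power at 40 Hz matches the analytic coefficient of the
  # periodic kernel train (period 25 ms)
  ker <- flickerlfp:::gt_kernel(gt, fs)
  period <- fs / 40
  train <- rep(0, 10 * fs)
  for (k in 0:(10 * 40 - 1)) {
    j0 <- round(k * period)
    klen <- min(length(ker), length(train) - j0)
    train[(j0 + 1):(j0 + klen)] <- train[(j0 + 1):(j0 + klen)] + ker[1:klen]
  }
  coef_obs <- abs(fft(clean)[401])   # 40 Hz bin of a 10 s window
  coef_ref <- abs(fft(train)[401])
  expect_equal(coef_obs, coef_ref, tolerance = 0.05)
  expect_gt(coef_ref, 0)
})

test_that("adapting mode scales the steady-state response by g_inf", {
  fs <- 500
  g_inf <- 0.2
  base <- list(amp = 30, freq = 12, decay = 0.03)
  tr <- make_trial_schedule("visual@40", n_each = 1, seed = 1)
  mk <- function(mode) {
    gt <- ground_truth(response_mode = mode, kernel = base,
                       adapt = list(g_inf = g_inf, tau = 3))
    make_lfp_session(gt, tr, fs = fs, seed = 2, return_clean = TRUE)$clean[1, ]
  }
  lin <- mk("linear_superposition")
  ada <- mk("adapting")
  # steady-state portion (after adaptation settles): amplitude ratio g_inf
  i0 <- round(tr$onset_s[1] * fs)
  late <- (i0 + 2 * fs):(i0 + 10 * fs)
  ratio <- sd(ada[late]) / sd(lin[late])
  expect_equal(ratio, g_inf, tolerance = 0.1 * g_inf)
})

test_that("spike generator matches von Mises phase statistics", {
  tr <- make_trial_schedule("visual@40", n_each = 10, seed = 2)
  stim <- tr[tr$modality != "none", ]
  # kappa = 0: homogeneous Poisson, vector strength near zero
  gt0 <- ground_truth(spike = list(rate = 20, kappa = 0, pref_phase = 0))
  sp0 <- make_spikes(gt0, tr, seed = 5)
  vs0 <- vector_strength(sp0, stim, 40)
  expect_lt(vs0$vs, 3 / sqrt(vs0$n_spikes))

  # large kappa: nearly all spikes at the preferred phase
  gt20 <- ground_truth(spike = list(rate = 20, kappa = 20, pref_phase = 1))
  sp20 <- make_spikes(gt20, tr, seed = 6)
  vs20 <- vector_strength(sp20, stim, 40)
  expect_gt(vs20$vs, 0.9)
  expect_equal(vs20$mean_phase, 1, tolerance = 0.1)

  expect_length(make_spikes(ground_truth(spike = list(rate = 0, kappa = 0,
                                                      pref_phase = 0)),
                            tr, seed = 1), 0)
})

test_that("IED generator respects trial rates and channel subsets", {
  tr <- make_trial_schedule("visual@40", n_each = 30, seed = 3)
  gt <- ground_truth(ied = list(rate_stim = 0.4, rate_baseline = 0.5,
                                channel_mean = 1.5, p_noise = 0,
                                noise_channels = 12))
  ev <- make_ieds(gt, tr, n_channels = 16, seed = 9)
  expect_true(all(lengths(ev$channels) >= 1))
  expect_true(!is.unsorted(ev$t_s))
  # all-noise generator: every event spans 12 channels
  gtn <- ground_truth(ied = list(rate_stim = 0.5, rate_baseline = 0.5,
                                 channel_mean = 1, p_noise = 1,
                                 noise_channels = 12))
  evn <- make_ieds(gtn, tr, n_channels = 16, seed = 2)
  expect_true(all(lengths(evn$channels) == 12))
  merged <- merge_and_filter(evn)
  expect_true(all(lengths(merged$channels) <= 11))  # every 12-wide event gone
})
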