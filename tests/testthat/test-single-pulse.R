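test_that("pulse EP extraction baseline-corrects and averages correctly", {
  fs <- 500
  n_pulses <- 12
  onsets <- 2 + (0:(n_pulses - 1)) * 1.6  # segments stay clear of neighbors
  n_time <- round((max(onsets) + 2) * fs)
  ker <- 8 * exp(-(0:(fs - 1)) / (0.04 * fs)) * sin(2 * pi * 10 * (0:(fs - 1)) / fs)
  x <- rep(0, n_time)
  for (o in onsets) x[round(o * fs) + seq_along(ker)] <- ker
  ch <- data.frame(contact_id = "c01", probe_id = "p01", probe_index = 1,
                   excluded = FALSE)
  rec <- new_recording(matrix(x, 1), fs, ch)
  ep <- pulse_ep(rec, onsets)
  # identical response every trial: SEM vanishes up to the slow-filter
  # memory (the 0.1 Hz high-pass leaves second-scale recovery tails)
  expect_lt(max(ep$sem), 1e-3 * max(abs(ker)))
  post <- ep$time >= 0 & ep$time < 1
  expect_gt(cor(ep$mean[1, post], ker), 0.99)
  # per-trial pre-onset mean is zero after baseline correction
  pre <- ep$time < 0
  pre_means <- apply(ep$trials[, 1, pre], 1, mean)
  expect_lt(max(abs(pre_means)), 1e-9 * max(abs(ker)))
  expect_error(pulse_ep(rec, c(2, 2.5)), "overlap")
})

test_that("injected kernel is recovered from noisy pulse trials", {
  gt <- ground_truth(response_mode = "linear_superposition",
                     kernel = list(amp = 10, freq = 12, decay = 0.05))
  ses <- make_pulse_session(gt, n_pulses = 200, fs = 250, seed = 31)
  ep <- pulse_ep(ses$rec, ses$onsets)
  ker <- flickerlfp:::gt_kernel(gt, 250)
  post <- ep$time >= 0 & ep$time < 1
  expect_gt(cor(ep$mean[1, post], ker), 0.95)
  amp <- pulse_amplitude(ep)
  expect_equal(unname(amp), max(abs(ker)), tolerance = 0.2)
})

test_that("pulse significance separates response from occluded control", {
  fs <- 200
  withr::with_seed(17, {
    occ <- matrix(rnorm(20 * fs), 20)
    stim <- matrix(rnorm(20 * fs), 20)
  })
  ker <- 5 * exp(-(0:(fs - 1)) / 10) * cos(2 * pi * 9 * (0:(fs - 1)) / fs)
  stim_ep <- sweep(stim, 2, ker, "+")
  r <- pulse_significance(stim_ep, occ, n_perm = 500, seed = 2)
  expect_equal(r$p_perm, 1 / 501)  # maximal separation
  # statistic antisymmetry under label swap
  r_ab <- pulse_significance(stim_ep, occ, n_perm = 10, seed = 1)
  r_ba <- pulse_significance(occ, stim_ep, n_perm = 10, seed = 1)
  expect_equal(r_ab$statistic, -r_ba$statistic)
  # null: no systematic significance
  r0 <- pulse_significance(stim, occ, n_perm = 500, seed = 3)
  expect_gt(r0$p_perm, 0.05)
})

test_that("amplitude normalization maps groups onto [0.001, 1] then log10", {
  expect_equal(normalize_amplitudes(c(2, 4)), c(-3, 0))
  # midpoint of [0, 10] -> (0.001 + 1)/2, log10 ~ -0.3005
  v <- normalize_amplitudes(c(0, 5, 10))
  expect_equal(v, c(-3, log10(0.5005), 0))
  # grouping is respected: each group's min maps to -3
  g <- normalize_amplitudes(c(1, 9, 100, 300), groups = c("a", "a", "b", "b"))
  expect_equal(g, c(-3, 0, -3, 0))
  expect_warning(cst <- normalize_amplitudes(c(5, 5)), "constant")
  expect_equal(cst, c(0, 0))
})

test_that("superposition simulation of a one-period sinusoid rebuilds a
           continuous sinusoid", {
  fs <- 1000
  f <- 40
  one_period <- sin(2 * pi * f * (0:(fs - 1)) / fs)
  one_period[(fs / f + 1):fs] <- 0   # 25 ms of sinusoid, then silence
  pulses <- matrix(rep(one_period, 10), 10, byrow = TRUE)
  sim <- simulate_superposition(pulses, fs, f = f, n_sim_trials = 3,
                                trial_len = 10, seed = 1)
  t10 <- (0:(10 * fs - 1)) / fs
  direct <- sin(2 * pi * f * t10)
  # interior samples match a directly synthesized sinusoid
  expect_equal(sim$data[1, 1, 1:(9 * fs)], direct[1:(9 * fs)],
               tolerance = 1e-9, ignore_attr = TRUE)
  # fold-change of simulated trials matches the direct sinusoid within 2%
  withr::with_seed(3, bl <- matrix(rnorm(3 * 10 * fs), 3))
  pow_bl <- power_at(multitaper_psd(tensor_from_matrix(bl, fs)), f)
  pow_sim <- power_at(multitaper_psd(sim), f)
  pow_dir <- power_at(multitaper_psd(
    tensor_from_matrix(rbind(direct, direct, direct), fs)), f)
  fc_sim <- fold_change(pow_sim[, 1], pow_bl[, 1], n_perm = 10)$fold_change
  fc_dir <- fold_change(pow_dir[, 1], pow_bl[, 1], n_perm = 10)$fold_change
  expect_equal(fc_sim, fc_dir, tolerance = 0.02)

  # all-zero pulse library: nothing simulated, nothing significant
  sim0 <- simulate_superposition(matrix(0, 5, fs), fs, seed = 2)
  expect_true(all(sim0$data == 0))

  # linearity: scaling the pulse library scales the trace
  sim2 <- simulate_superposition(2 * pulses, fs, f = f, n_sim_trials = 3,
                                 trial_len = 10, seed = 1)
  expect_equal(sim2$data, 2 * sim$data)
})

test_that("response classes cross pulse and flicker significance", {
  expect_equal(classify_response(0.01, 0.2), "pulse_only")
  expect_equal(classify_response(0.01, 0.01), "both")
  expect_equal(classify_response(0.2, 0.01), "flicker_only")
  expect_equal(classify_response(0.5, 0.5), "none")
})
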