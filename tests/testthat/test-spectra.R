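test_that("DPSS tapers match the reference solution and are orthonormal", {
  h <- dpss_tapers(64, nw = 3, k = 5)
  # frozen from scipy.signal.windows.dpss(64, 3, 5)
  ref <- rbind(
    c(0.0003564442, 0.0025072425, 0.0118392207, 0.0424152829, 0.1160563702),
    c(0.0673524676, 0.1551844506, 0.1947723213, 0.1108970401, -0.0512126087),
    c(0.2297040105, 0.0148643136, -0.1533556899, -0.0163593661, 0.1195237898))
  expect_equal(h[c(1, 16, 32), ], ref, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(crossprod(h), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # interpolated long-window tapers stay orthonormal and smooth
  hl <- dpss_tapers(5000, 3, 5)
  expect_equal(crossprod(hl), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(diff(hl[, 1]))), 0.01)
})

test_that("multitaper PSD localizes a sinusoid and is flat for white noise", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  p <- multitaper_psd(sin(2 * pi * 40 * t), fs)
  expect_equal(p$freq[which.max(p$psd)], 40, tolerance = 0.11)

  withr::with_seed(5, {
    x <- matrix(rnorm(50 * fs), 50)  # 50 one-second trials
  })
  pw <- multitaper_psd(x, fs, fmin = 10, fmax = 90)
  avg <- colMeans(pw$psd)
  expect_lt(max(avg) / min(avg), 2)
})

test_that("multitaper PSD conserves energy (Parseval)", {
  fs <- 512
  withr::with_seed(9, x <- rnorm(8 * fs))
  p <- multitaper_psd(x, fs, fmin = 0, fmax = fs / 2)
  expect_equal(sum(p$psd) * p$df, var(x), tolerance = 0.05)
})

test_that("fold-change follows mu_stim/mu_bl - 1 and its permutation test
           respects label exchange", {
  r <- fold_change(c(2, 2, 2), c(2, 2, 2), n_perm = 100, seed = 1)
  expect_equal(r$fold_change, 0)
  r <- fold_change(c(4, 4), c(2, 2), n_perm = 100, seed = 1)
  expect_equal(r$fold_change, 1)
  # invariance to global amplitude rescaling (power ratio)
  withr::with_seed(2, {
    a <- rexp(15); b <- rexp(15)
  })
  f1 <- fold_change(a, b, n_perm = 500, seed = 3)$fold_change
  f2 <- fold_change(7.3 * a, 7.3 * b, n_perm = 500, seed = 3)$fold_change
  expect_equal(f1, f2)
  # one-sided p flips about the permutation distribution on label swap
  p_ab <- fold_change(a, b, n_perm = 2000, seed = 4)$p_perm
  p_ba <- fold_change(b, a, n_perm = 2000, seed = 4)$p_perm
  expect_lt(abs(p_ab + p_ba - 1), 0.05)  # Monte-Carlo error of two draws
  expect_gt(p_ab, 0)  # add-one smoothing: never exactly zero
})

test_that("two-cycle evoked averaging reproduces a periodic template", {
  fs <- 1000
  f <- 40
  t <- (0:(10 * fs - 1)) / fs
  template <- sin(2 * pi * f * t) + 0.3 * sin(4 * pi * f * t)
  tt <- tensor_from_matrix(rbind(template, template, template), fs)
  ev <- evoked_two_cycle(tt, f)
  expect_equal(ev$n_windows, 3 * 399)  # 400 cycles, stride 1, need 2
  expect_lt(max(ev$sem), 1e-6)
  # the mean is one cycle repeated twice
  half <- length(ev$time) / 2
  expect_equal(ev$mean[1, 1:half], ev$mean[1, (half + 1):(2 * half)],
               tolerance = 1e-9, ignore_attr = TRUE)

  # pure noise: mean amplitude shrinks like 1/sqrt(n_windows)
  withr::with_seed(11, nz <- matrix(rnorm(20 * 10 * fs), 20))
  evn <- evoked_two_cycle(tensor_from_matrix(nz, fs), f)
  expect_lt(sd(evn$mean), 3 / sqrt(evn$n_windows))
})

test_that("PLV hits its endpoints and tracks von Mises concentration", {
  fs <- 500
  f <- 8
  t <- (0:(10 * fs - 1)) / fs
  delayed <- sin(2 * pi * f * (t - 0.013))
  tt <- tensor_from_matrix(rbind(delayed, delayed, delayed, delayed), fs)
  pl <- phase_locking(tt, f)
  expect_equal(unname(pl$plv), 1, tolerance = 1e-6)

  # equally spaced trial phases cancel exactly
  n <- 8
  m <- t(sapply(seq_len(n) - 1,
                function(j) sin(2 * pi * f * t + 2 * pi * j / n)))
  pl0 <- phase_locking(tensor_from_matrix(m, fs), f)
  expect_lt(pl0$plv, 1e-6)

  # von Mises trial phase offsets: PLV -> I1(k)/I0(k)
  kappa <- 2
  withr::with_seed(21, phis <- rvm(200, 0, kappa))
  mv <- t(sapply(phis, function(ph) sin(2 * pi * f * t + ph)))
  plv <- phase_locking(tensor_from_matrix(mv, fs), f)$plv
  expect_equal(unname(plv), besselI(kappa, 1) / besselI(kappa, 0),
               tolerance = 0.06)

  # invariance to a constant phase offset on every trial
  mv2 <- t(sapply(phis + 1.1, function(ph) sin(2 * pi * f * t + ph)))
  plv2 <- phase_locking(tensor_from_matrix(mv2, fs), f)$plv
  expect_equal(unname(plv2), unname(plv), tolerance = 1e-6)
})

test_that("Rayleigh test calibrates under uniform phases", {
  withr::with_seed(3, {
    ps <- replicate(400, rayleigh_test(runif(30, -pi, pi))$p)
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(rayleigh_test(rep(0.7, 50))$p, 1e-10)
})
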