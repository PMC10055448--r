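make_probe_rec <- function(samples, excluded = NULL, fs = 1000) {
  n <- nrow(samples)
  ch <- data.frame(contact_id = paste0("a", seq_len(n)), probe_id = "A",
                   probe_index = seq_len(n),
                   excluded = if (is.null(excluded)) FALSE else excluded)
  new_recording(samples, fs, ch)
}

test_that("Laplacian referencing follows the neighbor-average rule", {
  # 4-contact probe, one instant: ends bipolar, interiors Laplacian
  rec <- make_probe_rec(matrix(c(1, 2, 3, 4), 4, 1))
  out <- rereference_laplacian(rec)
  expect_equal(as.numeric(out$samples), c(-1, 0, 0, 1))

  # common signal across a probe vanishes at interior contacts
  s <- sin(seq(0, 4 * pi, length.out = 200))
  rec <- make_probe_rec(matrix(rep(s, each = 5), 5))
  out <- rereference_laplacian(rec)
  expect_lt(max(abs(out$samples[2:4, ])), 1e-12)

  # signal on one contact with silent neighbors passes through
  m <- matrix(0, 3, 200); m[2, ] <- s
  out <- rereference_laplacian(make_probe_rec(m))
  expect_equal(out$samples[2, ], s)
})

test_that("Laplacian skips excluded neighbors and is linear", {
  # contact 2 excluded: contact 3's neighbors become 1 and 4
  m <- matrix(rnorm(5 * 50), 5)
  rec <- make_probe_rec(m, excluded = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- rereference_laplacian(rec)
  expect_equal(out$samples[3, ], m[3, ] - (m[1, ] + m[4, ]) / 2)
  expect_equal(out$samples[1, ], m[1, ] - m[3, ])  # bipolar past exclusion

  # linearity: L(ax + by) = a L(x) + b L(y)
  x <- matrix(rnorm(4 * 30), 4); y <- matrix(rnorm(4 * 30), 4)
  lx <- rereference_laplacian(make_probe_rec(x))$samples
  ly <- rereference_laplacian(make_probe_rec(y))$samples
  lxy <- rereference_laplacian(make_probe_rec(2 * x - 3 * y))$samples
  expect_equal(lxy, 2 * lx - 3 * ly)
})

test_that("contacts without usable neighbors are excluded with warning", {
  ch <- data.frame(contact_id = c("a1", "b1", "b2"),
                   probe_id = c("A", "B", "B"), probe_index = c(1, 1, 2),
                   excluded = FALSE)
  rec <- new_recording(matrix(rnorm(3 * 10), 3), 1000, ch)
  expect_warning(out <- rereference_laplacian(rec), "no usable neighbor")
  expect_true(out$channels$excluded[1])   # single-contact probe
  expect_false(any(out$channels$excluded[2:3]))
})

test_that("segmentation produces padded per-condition tensors", {
  fs <- 1000
  rec <- make_probe_rec(matrix(rnorm(2 * 60 * fs), 2), fs = fs)
  trials <- trial_table(c("visual", "none"), c("40", "baseline"),
                        c(5, 20), 10)
  segs <- segment_trials(rec, trials, pad = 1)
  expect_named(segs, c("visual@40", "none@baseline"))
  expect_equal(dim(segs[["visual@40"]]$data), c(1, 2, 12000))
  segs0 <- segment_trials(rec, trials, pad = 0)
  expect_equal(dim(segs0[["visual@40"]]$data)[3], 10 * fs)
  # exact sample content, 0-based half-open windows
  expect_equal(segs0[["visual@40"]]$data[1, 1, ],
               rec$samples[1, (5 * fs + 1):(15 * fs)])

  bad <- trial_table("visual", "40", 0, 10)
  expect_error(segment_trials(rec, bad, pad = 1), "exceeds recording")
  expect_error(segment_trials(rec, trial_table("visual", "40", 55, 10)),
               "exceeds recording")
})

test_that("excluded channels never reach downstream tensors", {
  fs <- 1000
  rec <- make_probe_rec(matrix(rnorm(3 * 30 * fs), 3), fs = fs,
                        excluded = c(FALSE, TRUE, FALSE))
  segs <- segment_trials(rec, trial_table("visual", "40", 5, 10), pad = 1)
  expect_equal(dimnames(segs[[1]]$data)[[2]], c("a1", "a3"))
})

test_that("flicker filtering removes DC, passes 40 Hz, rejects 500 Hz", {
  fs <- 2048
  t <- (0:(12 * fs - 1)) / fs
  wrap <- function(v) {
    tt <- tensor_from_matrix(matrix(v, 1), fs)
    tt$pad <- 1
    tt
  }
  # DC offset is removed by the per-segment baseline correction
  out <- filter_flicker(wrap(rep(5, length(t))))
  expect_lt(abs(mean(out$data)), 1e-9 * 5)
  expect_lt(max(abs(out$data)), 0.01 * 5)  # filter transients stay in pads

  s40 <- sin(2 * pi * 40 * t)
  out <- filter_flicker(wrap(s40))
  ref <- s40[(fs + 1):(11 * fs)]
  gain <- sum(out$data[1, 1, ] * ref) / sum(ref^2)
  expect_lt(abs(gain - 1), 0.05)

  s500 <- sin(2 * pi * 500 * t)
  out <- filter_flicker(wrap(s500))
  atten_db <- 20 * log10(sd(out$data[1, 1, ]) / sd(s500))
  expect_lt(atten_db, -20)
})

test_that("filtering clips the upper edge when fs cannot support it", {
  tt <- tensor_from_matrix(matrix(rnorm(500 * 12), 1), 500)
  tt$pad <- 1
  expect_warning(filter_flicker(tt), "clipped")
})

test_that("trial balancing equalizes counts deterministically", {
  fs <- 200
  mk <- function(n) tensor_from_matrix(matrix(rnorm(n * fs), n), fs)
  tens <- list(a = mk(15), b = mk(15), bl = mk(180))
  bal <- balance_trials(tens, seed = 7)
  expect_true(all(vapply(bal, function(x) dim(x$data)[1], numeric(1)) == 15))
  bal2 <- balance_trials(tens, seed = 7)
  expect_identical(attr(bal$bl, "selected"), attr(bal2$bl, "selected"))
  expect_identical(bal$bl$data, bal2$bl$data)
  # equal counts: identity, order preserved
  eq <- balance_trials(list(a = mk(5), b = mk(5)), seed = 1)
  expect_identical(attr(eq$a, "selected"), 1:5)
})
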