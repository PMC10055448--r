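#' Zero-phase Butterworth filtering for LFP preprocessing
#'
#' Filters are designed as cascades of second-order sections (biquads)
#' rather than single high-order polynomials: the band edges used here
#' (0.1 Hz and 2 Hz at kilohertz sampling rates) make the polynomial
#' transfer-function form numerically unstable, while the biquad cascade
#' is well conditioned. Each section is the bilinear transform of an
#' analog Butterworth pole pair; cascading the sections reproduces the
#' full Butterworth magnitude response. Zero-phase response is obtained
#' by forward-backward application, which preserves the timing of evoked
#' waveforms that are later averaged time-locked to stimulus onsets.
#'
#' @param order filter order; must be even (pole pairs only).
#' @param fc cutoff frequency in Hz (-3 dB point of the one-way filter).
#' @param fs sampling rate in Hz.
#' @param type "low" or "high".
#' @return object of class `butter_sos`: list of biquad sections, each
#'   with numerator `b` and denominator `a` coefficients.
#' @keywords internal
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 2, order %% 2 == 0, fc > 0, fc < fs / 2)
  w0 <- 2 * pi * fc / fs
  cw <- cos(w0)
  sw <- sin(w0)
  n_sec <- order / 2
  # Butterworth pole-pair quality factors: Q_k = 1 / (2 sin(theta_k))
  k <- seq_len(n_sec)
  theta <- pi * (2 * k - 1) / (2 * order)
  q <- 1 / (2 * sin(theta))
  sections <- lapply(q, function(qk) {
    alpha <- sw / (2 * qk)
    a <- c(1 + alpha, -2 * cw, 1 - alpha)
    if (type == "low") {
      b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
    } else {
      b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
    }
    list(b = b / a[1], a = a / a[1])
  })
  structure(list(sections = sections, fc = fc, fs = fs, type = type,
                 order = order),
            class = "butter_sos")
}

#' Magnitude response of a biquad cascade
#'
#' @param filt a `butter_sos` object.
#' @param f frequencies in Hz at which to evaluate.
#' @param zero_phase if TRUE, square the magnitude (forward-backward
#'   application).
#' @return magnitude response (linear scale) at `f`.
#' @keywords internal
sos_response <- function(filt, f, zero_phase = FALSE) {
  z <- exp(-2i * pi * f / filt$fs)
  h <- rep(1 + 0i, length(f))
  for (s in filt$sections) {
    num <- s$b[1] + s$b[2] * z + s$b[3] * z^2
    den <- s$a[1] + s$a[2] * z + s$a[3] * z^2
    h <- h * num / den
  }
  m <- Mod(h)
  if (zero_phase) m^2 else m
}

#' Apply a biquad cascade forward-backward (zero phase)
#'
#' Forward-backward filtering with odd-reflection end padding (the
#' padding absorbs the filter's start-up transient; its length is three
#' settling times of the slowest edge, capped at the signal length), so
#' the effective magnitude response is the squared cascade response and
#' the phase response is identically zero.
#'
#' @param x numeric vector, or matrix with one signal per row.
#' @param filt a `butter_sos` object, or a list of them applied in
#'   sequence (e.g. high-pass then low-pass for a band-pass).
#' @return filtered data, same shape as `x`.
#' @keywords internal
filtfilt_sos <- function(x, filt) {
  filts <- if (inherits(filt, "butter_sos")) list(filt) else filt
  fs <- filts[[1]]$fs
  fc_min <- min(vapply(filts, function(f) f$fc, numeric(1)))
  apply_one <- function(v) {
    n <- length(v)
    np <- min(n - 1, ceiling(3 * fs / fc_min))
    pre <- 2 * v[1] - v[(np + 1):2]
    post <- 2 * v[n] - v[(n - 1):(n - np)]
    w <- c(pre, v, post)
    for (ft in filts) {
      for (s in ft$sections) {
        w <- sos_pass(s, sos_pass(s, w, forward = TRUE), forward = FALSE)
      }
    }
    w[(np + 1):(np + n)]
  }
  if (is.matrix(x)) {
    t(apply(x, 1, apply_one))
  } else {
    apply_one(x)
  }
}

# single biquad pass with steady-state initial conditions matched to
# the first sample, so a constant input produces no start-up transient
sos_pass <- function(s, v, forward = TRUE) {
  if (!forward) v <- rev(v)
  dc <- sum(s$b) / sum(s$a)
  out <- as.numeric(signal::filter(s$b, s$a, v,
                                   init.x = rep(v[1], 2),
                                   init.y = rep(dc * v[1], 2)))
  if (!forward) rev(out) else out
}
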