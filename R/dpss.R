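#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers for a window of `n` samples and
#' time-bandwidth product `nw`, via the symmetric tridiagonal eigenvalue
#' formulation (diagonal `((n-1-2t)/2)^2 cos(2 pi W)`, off-diagonal
#' `t (n-t) / 2`). For long windows the tapers are computed on a shorter
#' grid and spline-interpolated to `n` samples, then re-orthonormalized;
#' the taper shapes are smooth functions of `t/n` at fixed `nw`, so the
#' interpolation error is negligible at analysis lengths.
#'
#' Tapers are normalized to unit energy (`sum(h^2) == 1`) and returned
#' with the conventional sign (non-negative mean for symmetric tapers,
#' positive initial slope for antisymmetric ones). Results are cached
#' per `(n, nw, k)` within the session.
#'
#' @param n window length in samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5, i.e. `2*nw - 1`).
#' @param max_exact longest window solved exactly; longer windows are
#'   interpolated from this length.
#' @return `n` x `k` matrix, one taper per column.
#' @export
#' @examples
#' h <- dpss_tapers(512, nw = 3, k = 5)
#' round(crossprod(h), 10)  # identity: orthonormal tapers
dpss_tapers <- function(n, nw = 3, k = 5, max_exact = 1024L) {
  stopifnot(n >= 8, nw > 0, k >= 1, k <= n)
  key <- paste(n, nw, k, sep = "_")
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (n <= max_exact) {
    h <- dpss_exact(n, nw, k)
  } else {
    h0 <- dpss_tapers(max_exact, nw, k, max_exact = max_exact)
    t0 <- (seq_len(max_exact) - 0.5) / max_exact
    t1 <- (seq_len(n) - 0.5) / n
    h <- apply(h0, 2, function(col) {
      stats::spline(t0, col, xout = t1, method = "natural")$y
    })
    # re-orthonormalize after interpolation (Gram-Schmidt)
    h <- qr.Q(qr(h))
    h <- fix_taper_sign(h)
  }
  assign(key, h, envir = .dpss_cache)
  h
}

.dpss_cache <- new.env(parent = emptyenv())

dpss_exact <- function(n, nw, k) {
  w <- nw / n
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- t[-1] * (n - t[-1]) / 2
  m <- diag(d)
  m[cbind(2:n, 1:(n - 1))] <- e
  m[cbind(1:(n - 1), 2:n)] <- e
  es <- eigen(m, symmetric = TRUE)
  h <- es$vectors[, seq_len(k), drop = FALSE]
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  fix_taper_sign(h)
}

fix_taper_sign <- function(h) {
  for (j in seq_len(ncol(h))) {
    s <- sum(h[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) h[, j] <- -h[, j]
    } else if (h[2, j] - h[1, j] < 0) {
      h[, j] <- -h[, j]
    }
  }
  h
}
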