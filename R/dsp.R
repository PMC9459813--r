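# Internal signal-processing primitives shared by resampling, feature
# extraction and step detection. All filters here are zero-phase so that
# detected event times are not biased by filter group delay.

#' Run code with a temporary RNG state
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state so
#' that seeded package functions do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Steady-state initial filter state (direct form II transposed) so that a
# constant input passes through an IIR filter without a startup transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[2:n]
  if (n > 2) A[2:(n - 1), 1:(n - 2)] <- diag(n - 2)
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Single-pass IIR filter (direct form II transposed) with explicit initial
# state. Plain R loop; filter orders here are <= 8 so this is cheap.
lin_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  N <- length(x)
  y <- numeric(N)
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  for (m in seq_len(N)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    if (n > 2) {
      for (i in 1:(n - 2)) z[i] <- b[i + 1] * xm + z[i + 1] - a[i + 1] * ym
    }
    z[n - 1] <- b[n] * xm - a[n] * ym
    y[m] <- ym
  }
  y
}

# Zero-phase forward-backward filtering with odd (point-reflected) edge
# extension and steady-state initial conditions, so constants pass exactly
# and edge transients are suppressed.
filtfilt_zi <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  pad <- 3 * (nfilt - 1)
  N <- length(x)
  if (N <= pad) stop("signal too short for zero-phase filtering (need > ", pad, " samples)")
  xpad <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[N] - x[(N - 1):(N - pad)])
  zi <- lfilter_zi(b, a)
  y <- lin_filter(b, a, xpad, zi * xpad[1])
  y <- rev(lin_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + N)]
}

# Extend a series at both ends by Burg linear prediction. Band-limited
# signals are locally well approximated by a low-order autoregression, so
# this extension avoids the edge kinks of mirror padding when a filter or
# interpolation kernel reaches past the recording boundary.
ar_extend <- function(x, pad, order = 24) {
  N <- length(x)
  mu <- mean(x)
  flat <- list(pre = rep(x[1], pad), post = rep(x[N], pad))
  if (stats::sd(x) < 1e-12 || N < 3 * order) return(flat)
  xc <- x - mu
  ar <- tryCatch(
    stats::ar.burg(xc, aic = FALSE, order.max = order, demean = FALSE)$ar,
    error = function(e) numeric(0)
  )
  if (!length(ar) || any(!is.finite(ar))) return(flat)
  p <- length(ar)
  fwd <- numeric(pad)
  buf <- xc[(N - p + 1):N]
  for (i in seq_len(pad)) {
    v <- sum(ar * rev(buf))
    fwd[i] <- v
    buf <- c(buf[-1], v)
  }
  # a stationary AR process run backwards obeys the same recursion
  bwd <- numeric(pad)
  buf <- rev(xc[1:p])
  for (i in seq_len(pad)) {
    v <- sum(ar * rev(buf))
    bwd[i] <- v
    buf <- c(buf[-1], v)
  }
  out <- list(pre = rev(bwd) + mu, post = fwd + mu)
  # guard against unstable extrapolation
  rng <- diff(range(x))
  lim <- range(x) + c(-2, 2) * max(rng, 1e-6)
  if (any(!is.finite(c(out$pre, out$post))) ||
      any(c(out$pre, out$post) < lim[1]) || any(c(out$pre, out$post) > lim[2])) {
    return(flat)
  }
  out
}

# Kaiser-windowed sinc interpolation of a uniformly sampled signal at
# arbitrary times. Weights are renormalised to sum to one so a constant
# signal is reproduced exactly. `x` must already be padded by at least
# `half_width` samples on each side relative to the times requested.
sinc_interp_padded <- function(xp, fs, t_out, offset, half_width = 48, beta = 20) {
  ib0 <- besselI(beta, 0)
  vapply(t_out, function(t) {
    k0 <- floor(t * fs)
    ks <- (k0 - half_width + 1):(k0 + half_width)
    u <- t * fs - ks
    w <- ifelse(abs(u) < 1e-12, 1, sin(pi * u) / (pi * u))
    kb <- 1 - (u / half_width)^2
    kb[kb < 0] <- 0
    w <- w * besselI(beta * sqrt(kb), 0) / ib0
    w <- w / sum(w)
    sum(w * xp[ks + offset + 1])
  }, 0.0)
}

# Anti-aliased zero-phase resampling of one channel from fs to target_fs.
resample_channel <- function(x, fs, target_fs, half_width = 48, beta = 20) {
  if (target_fs == fs) return(x)
  N <- length(x)
  pad <- half_width + 32
  ext <- ar_extend(x, pad)
  xe <- c(ext$pre, x, ext$post)
  bf <- signal::butter(8, 0.9 * target_fs / fs)
  xf <- filtfilt_zi(bf$b, bf$a, xe)
  n_out <- floor((N - 1) * target_fs / fs) + 1
  t_out <- (0:(n_out - 1)) / target_fs + pad / fs
  sinc_interp_padded(xf, fs, t_out, offset = 0, half_width = half_width, beta = beta)
}

# Gaussian smoothing with kernel standard deviation scale_s / 4 (the
# stated scale approximates the kernel's full support). Constant-padded.
gaussian_smooth <- function(x, fs, scale_s) {
  sig <- scale_s / 4
  hw <- max(1L, ceiling(4 * sig * fs))
  u <- (-hw:hw) / fs
  k <- exp(-u^2 / (2 * sig^2))
  k <- k / sum(k)
  xp <- c(rep(x[1], hw), x, rep(x[length(x)], hw))
  y <- as.numeric(stats::filter(xp, k, method = "convolution", sides = 2))
  y[(hw + 1):(hw + length(x))]
}

#' Continuous Gaussian-derivative wavelet response
#'
#' Convolves a signal with a first-derivative-of-Gaussian mother wavelet.
#' The scale is given as the pseudo-period of peak frequency response: the
#' kernel standard deviation is `scale_s / (2 * pi)`, which places the peak
#' of the wavelet's frequency response at `1 / scale_s` Hz.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param scale_s Wavelet scale as a pseudo-period in seconds.
#' @return Numeric vector of wavelet coefficients, same length as `x`.
#' @examples
#' t <- (0:499) / 50
#' w <- cwt_gauss_deriv(sin(2 * pi * 2 * t), fs = 50, scale_s = 0.5)
#' @export
cwt_gauss_deriv <- function(x, fs, scale_s) {
  stopifnot(is.numeric(x), length(x) >= 4, fs > 0, scale_s > 0)
  sig <- scale_s / (2 * pi)
  hw <- max(2L, ceiling(5 * sig * fs))
  u <- (-hw:hw) / fs
  k <- -(u / sig^2) * exp(-u^2 / (2 * sig^2)) / fs
  xp <- c(rep(x[1], hw), x, rep(x[length(x)], hw))
  # stats::filter computes sum(f[j] * x[i + o + 1 - j]): a true convolution,
  # so the antisymmetric kernel is applied with its stated orientation
  y <- as.numeric(stats::filter(xp, rev(k), method = "convolution", sides = 2))
  y[(hw + 1):(hw + length(x))]
}

# Local maxima with topographic prominence, minimum separation enforced
# greedily in order of decreasing prominence.
find_peaks <- function(y, min_sep = 1L, min_prominence = 0) {
  n <- length(y)
  d <- diff(y)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(idx)) return(data.frame(idx = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    higher_l <- which(y[1:i] > y[i])
    left_min <- if (length(higher_l)) min(y[max(higher_l):i]) else min(y[1:i])
    higher_r <- which(y[i:n] > y[i])
    right_min <- if (length(higher_r)) min(y[i:(i + min(higher_r) - 1)]) else min(y[i:n])
    y[i] - max(left_min, right_min)
  }, 0.0)
  keep <- prom >= min_prominence
  idx <- idx[keep]
  prom <- prom[keep]
  if (!length(idx)) return(data.frame(idx = integer(0), prominence = numeric(0)))
  ord <- order(-prom)
  sel <- integer(0)
  for (j in ord) {
    if (!length(sel) || all(abs(idx[j] - idx[sel]) >= min_sep)) sel <- c(sel, j)
  }
  sel <- sort(sel)
  data.frame(idx = idx[sel], prominence = prom[sel])
}

# Cumulative composite-trapezoid integral of a uniformly sampled signal.
cumtrapz_uniform <- function(x, fs) {
  c(0, cumsum((x[-1] + x[-length(x)]) / 2)) / fs
}
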