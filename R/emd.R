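## Empirical mode decomposition by cubic-spline envelope sifting, and the
## discrete analytic signal. No randomness anywhere: extraction is
## bit-reproducible.

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  d <- diff(x)
  # collapse plateaus: treat zero slopes as continuing the previous trend
  for (i in seq_along(d)) {
    if (d[i] == 0 && i > 1L) d[i] <- d[i - 1L]
  }
  s <- sign(d)
  idx <- which(s[-1] != s[-length(s)]) + 1L
  list(
    maxima = idx[s[idx - 1L] > 0],
    minima = idx[s[idx - 1L] < 0]
  )
}

# mirror up to `k` extrema beyond each end so the envelope spline covers [1, n]
extend_extrema <- function(t, v, n, k = 2L) {
  if (length(t) == 0L) {
    return(list(t = t, v = v))
  }
  head_k <- seq_len(min(k, length(t)))
  tail_k <- seq(max(1L, length(t) - k + 1L), length(t))
  t_ext <- c(2 - rev(t[head_k]), t, 2 * n - rev(t[tail_k]))
  v_ext <- c(rev(v[head_k]), v, rev(v[tail_k]))
  keep <- !duplicated(t_ext)
  list(t = t_ext[keep], v = v_ext[keep])
}

envelope_mean <- function(h) {
  n <- length(h)
  ex <- local_extrema(h)
  if (length(ex$maxima) < 1L || length(ex$minima) < 1L) {
    return(NULL)
  }
  up <- extend_extrema(ex$maxima, h[ex$maxima], n)
  lo <- extend_extrema(ex$minima, h[ex$minima], n)
  if (length(up$t) < 2L || length(lo$t) < 2L) {
    return(NULL)
  }
  upper <- stats::splinefun(up$t, up$v, method = "fmm")(seq_len(n))
  lower <- stats::splinefun(lo$t, lo$v, method = "fmm")(seq_len(n))
  (upper + lower) / 2
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by iterative
#' sifting: cubic-spline envelopes through local maxima and minima (with the
#' two outermost extrema mirror-extended past each end), subtracting the
#' envelope mean until the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sift_tol` or `max_sift` sifts.
#' Decomposition stops when the residual has no full pair of extrema (is
#' monotonic) or `max_imf` IMFs have been extracted. The IMFs plus residual
#' reconstruct the input exactly (sums of differences), and a constant or
#' too-short series yields zero IMFs with the series as residual.
#'
#' @param x Numeric series (the decomposition is meaningful for length >= 4).
#' @param max_imf Maximum number of IMFs to extract.
#' @param sift_tol Cauchy stopping tolerance for sifting.
#' @param max_sift Maximum sifting iterations per IMF.
#' @return An object of class `emd`: list with `imfs` (length-n vectors, possibly
#'   empty list), `residual`, and the input `x`.
#' @export
emd <- function(x, max_imf = 10L, sift_tol = 0.2, max_sift = 50L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  imfs <- list()
  residual <- x
  while (length(imfs) < max_imf) {
    h <- residual
    m <- envelope_mean(h)
    if (is.null(m)) break # monotonic / too few extrema: done
    for (s in seq_len(max_sift)) {
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / sum(h^2)
      h <- h_new
      if (sd_crit < sift_tol) break
      m <- envelope_mean(h)
      if (is.null(m)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  structure(list(imfs = imfs, residual = residual, x = x), class = "emd")
}

#' @export
print.emd <- function(x, ...) {
  cat(
    "EMD of a length-", length(x$x), " series: ", length(x$imfs),
    " IMF(s) + residual\n",
    sep = ""
  )
  invisible(x)
}

#' Discrete analytic signal via the Hilbert transform
#'
#' FFT implementation: negative frequencies are zeroed, positive doubled.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  d_adj <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d_adj))
}

#' Hilbert spectral features of an IMF set
#'
#' For IMFs 1..8 (absent ones contribute zeros) the analytic signal yields
#' instantaneous amplitude and phase; four statistics are emitted per IMF:
#' mean and variance of the amplitude, mean instantaneous frequency (one-sided
#' unwrapped phase differences in cycles/step, first and last samples
#' excluded), and the IMF's energy as a fraction of the input series' energy.
#'
#' @param decomposition An `emd` object.
#' @param n_imf Number of IMF slots (default 8).
#' @return Numeric vector of length `4 * n_imf`, IMF-major:
#'   `amp_mean, amp_var, freq_mean, energy_frac` per IMF.
#' @export
hilbert_features <- function(decomposition, n_imf = 8L) {
  stopifnot(inherits(decomposition, "emd"))
  total_energy <- sum(decomposition$x^2)
  out <- numeric(4L * n_imf)
  for (k in seq_len(min(n_imf, length(decomposition$imfs)))) {
    imf <- decomposition$imfs[[k]]
    z <- analytic_signal(imf)
    amp <- Mod(z)
    phase <- unwrap_phase(Arg(z))
    freq <- diff(phase) / (2 * pi)
    # drop the first and last sample's contribution (edge artifacts)
    if (length(freq) > 2L) freq <- freq[2:(length(freq) - 1L)]
    base <- 4L * (k - 1L)
    out[base + 1L] <- mean(amp)
    out[base + 2L] <- var0(amp)
    out[base + 3L] <- if (length(freq) > 0L) mean(freq) else 0
    out[base + 4L] <- if (total_energy > 0) sum(imf^2) / total_energy else 0
  }
  out
}
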