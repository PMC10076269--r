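# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
stop_fibrescope <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fibrescope_error")))
}

# Evaluate expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched so package randomness never perturbs user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 2-D FFTs; stats::fft handles the multidimensional case directly.
#' @noRd
fft2 <- function(x) stats::fft(x)

#' @noRd
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT sample frequencies in cycles per sample, matching the layout of fft().
#' @noRd
fft_freq <- function(n) {
  f <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / n
  f
}

# Band-limited (sinc) interpolation of a square complex field by FFT
# zero-padding; exact for fields whose spectrum lies inside Nyquist. The
# upsampled sample j sits at axis[1] + (j - 1) * pitch / factor.
#' @noRd
fft_upsample <- function(field, factor) {
  n <- nrow(field)
  if (factor == 1L) return(field)
  f <- fft2(field)
  nf <- n * factor
  h <- n %/% 2
  lo <- seq_len(h)
  hi <- (h + 1):n
  big <- matrix(0 + 0i, nf, nf)
  big[lo, lo] <- f[lo, lo]
  big[lo, (nf - (n - h) + 1):nf] <- f[lo, hi]
  big[(nf - (n - h) + 1):nf, lo] <- f[hi, lo]
  big[(nf - (n - h) + 1):nf, (nf - (n - h) + 1):nf] <- f[hi, hi]
  ifft2(big) * factor^2
}

# Total power of a sampled field: sum |E|^2 * pitch^2.
#' @noRd
field_power <- function(field, pitch) sum(Mod(field)^2) * pitch^2

#' @noRd
normalize_power <- function(field, pitch) {
  p <- field_power(field, pitch)
  if (p == 0) stop_fibrescope("cannot normalise a zero field", "degenerate_input")
  field / sqrt(p)
}

# Complex standard normal matrix.
#' @noRd
crandn <- function(n, m) {
  matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)) /
           sqrt(2), n, m)
}

# Haar-distributed random unitary via QR of a complex Ginibre matrix with the
# standard phase fix (diagonal of R made real positive).
#' @noRd
random_unitary <- function(n) {
  z <- crandn(n, n)
  qr_z <- qr(z)
  q <- qr.Q(qr_z)
  r <- qr.R(qr_z)
  d <- diag(r)
  q %*% diag(d / Mod(d), n, n)
}

# Fractional power of a unitary matrix along the geodesic from the identity:
# U^t = W diag(exp(i t theta)) W^H, exactly unitary for every t.
#' @noRd
unitary_power <- function(u, t) {
  if (t == 0) return(diag(1 + 0i, nrow(u)))
  if (t == 1) return(u)
  e <- eigen(u)
  theta <- Arg(e$values)
  e$vectors %*% (exp(1i * t * theta) * Conj(t(e$vectors)))
}

# Parabolic (three-point) refinement of an extremum on a uniform grid.
# Returns the fractional offset in grid steps from the central point.
#' @noRd
parabolic_offset <- function(y_minus, y0, y_plus) {
  denom <- y_minus - 2 * y0 + y_plus
  if (denom == 0) return(0)
  off <- 0.5 * (y_minus - y_plus) / denom
  max(min(off, 1), -1)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
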