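# Input-modulation basis, kinoform synthesis by phase conjugation, and
# binary off-axis (DMD-style) amplitude hologram encoding / decoding.

#' Calibration input basis of tilted truncated plane waves
#'
#' Builds the ordered set of input fields used for transmission-matrix
#' acquisition: plane waves truncated to the fibre core aperture, with
#' transverse tilt wavenumbers taken from the grid's discrete (FFT) tilt
#' lattice restricted to the fibre NA disk, ordered spirally from zero tilt
#' (by tilt magnitude, then angle).
#'
#' @param n_elements Number of basis elements.
#' @param grid A [field_grid()].
#' @param spec A [fiber_spec()]; bounds the tilts via `|k_t| <= k * na`.
#' @return An object of class `input_basis` with `fields` (matrix, one
#'   flattened unit-power field per column) and `tilts` (2 x n matrix of
#'   transverse wavenumbers in rad/um).
#' @export
make_input_basis <- function(n_elements, grid, spec) {
  stopifnot(inherits(grid, "field_grid"), inherits(spec, "fiber_spec"))
  if (!is_scalar_number(n_elements) || n_elements < 1)
    stop_fibrescope("n_elements must be >= 1", "invalid_spec")
  n_elements <- as.integer(n_elements)
  k_na <- 2 * pi * spec$na / spec$wavelength
  f <- fft_freq(grid$n_pixels) / grid$pitch       # cycles per um
  kx <- rep(2 * pi * f, times = grid$n_pixels)
  ky <- rep(2 * pi * f, each = grid$n_pixels)
  keep <- sqrt(kx^2 + ky^2) <= k_na
  kx <- kx[keep]; ky <- ky[keep]
  if (n_elements > length(kx))
    stop_fibrescope(sprintf(
      "n_elements %d exceeds the %d distinguishable tilts inside the NA disk",
      n_elements, length(kx)), "invalid_spec")
  # Spiral order (radius, then angle), then subsample the spiral evenly so a
  # reduced element count still spans the whole NA disk instead of only its
  # low-angle centre.
  ord <- order(sqrt(kx^2 + ky^2), atan2(ky, kx))
  pick <- unique(round(seq(1, length(kx), length.out = n_elements)))
  kx <- kx[ord][pick]
  ky <- ky[ord][pick]
  n_elements <- length(pick)

  co <- grid_coords(grid)
  aperture <- as.vector(co$r) <= spec$core_diameter / 2
  x <- as.vector(co$x); y <- as.vector(co$y)
  fields <- matrix(0i, grid$n_pixels^2, n_elements)
  for (j in seq_len(n_elements)) {
    e <- exp(1i * (kx[j] * x + ky[j] * y))
    e[!aperture] <- 0
    fields[, j] <- as.vector(normalize_power(e, grid$pitch))
  }
  structure(list(fields = fields, tilts = rbind(kx, ky), grid = grid,
                 spec = spec, n_elements = n_elements),
            class = "input_basis")
}

#' Kinoform for a single focus by phase conjugation
#'
#' Conjugates the transmission-matrix row of the requested output sample:
#' the modulation `sum_j conj(T[target, j]) * basis_j`, normalised to unit
#' power. Applying the forward operator to it maximises the intensity at the
#' target among phase-conjugation solutions.
#'
#' @param tm A [acquire_tm()] result.
#' @param target Output sample, either a linear pixel index into the output
#'   grid or a `(row, col)` pair.
#' @return An object of class `modulation` (`kind = "complex"`) with the
#'   rendered `field` and the input-basis coefficient vector `coef`.
#' @export
phase_conjugate_kinoform <- function(tm, target) {
  stopifnot(inherits(tm, "transmission_matrix"))
  idx <- resolve_target(target, tm$output_grid)
  kappa <- Conj(tm$matrix[idx, ])
  field <- matrix(tm$input_basis$fields %*% kappa, tm$output_grid$n_pixels)
  p <- field_power(field, tm$output_grid$pitch)
  if (p == 0) stop_fibrescope("degenerate kinoform (zero row)", "degenerate_input")
  modulation(field / sqrt(p), kind = "complex", coef = kappa / sqrt(p),
             grid = tm$output_grid)
}

#' @noRd
resolve_target <- function(target, grid) {
  n <- grid$n_pixels
  if (length(target) == 2L) target <- (target[2] - 1L) * n + target[1]
  target <- as.integer(target)
  if (is.na(target) || target < 1L || target > n^2)
    stop_fibrescope("target outside the output grid", "index_error")
  target
}

#' Modulation container
#'
#' @param field Complex (or binary 0/1) matrix on the modulation plane.
#' @param kind `"complex"` or `"binary"`.
#' @param coef Optional input-basis coefficients of a kinoform.
#' @param grid Optional [field_grid()].
#' @return An object of class `modulation`.
#' @export
modulation <- function(field, kind = c("complex", "binary"), coef = NULL,
                       grid = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary" && !all(field %in% c(0, 1)))
    stop_fibrescope("binary modulation must take values {0, 1}", "invalid_spec")
  structure(list(field = field, kind = kind, coef = coef, grid = grid),
            class = "modulation")
}

#' Off-axis carrier for binary hologram encoding
#'
#' @param freq Carrier frequency vector in cycles per pixel (2 components);
#'   magnitude must lie in `(0, 0.5]`. Default: 0.125 cycles/pixel along both
#'   axes (8-pixel period), which keeps the per-pixel carrier phase step small
#'   enough that binarisation quantisation stays out of the first-order band.
#' @param duty_max Maximum mirror-on duty fraction used by the amplitude
#'   mapping.
#' @return An object of class `carrier_spec`.
#' @export
carrier_spec <- function(freq = c(0.125, 0.125), duty_max = 0.5) {
  mag <- sqrt(sum(freq^2))
  if (!(mag > 0 && mag <= 0.5))
    stop_fibrescope("carrier magnitude must lie in (0, 0.5] cycles/pixel",
                    "invalid_spec")
  structure(list(freq = freq, duty_max = duty_max, magnitude = mag),
            class = "carrier_spec")
}

#' Binary off-axis (Lee-style) hologram encoding
#'
#' Encodes amplitude and phase of a complex modulation into a binary mirror
#' pattern whose first diffraction order at the carrier frequency carries the
#' field: mirror ON where
#' `cos(2 pi f . x + arg(m)) > cos(pi q)`, with duty
#' `q = asin(|m| / max|m|) / pi` so the first-order amplitude is proportional
#' to `|m|`.
#'
#' @param mod A complex [modulation()].
#' @param carrier A [carrier_spec()].
#' @return A binary [modulation()].
#' @export
binarize_lee <- function(mod, carrier = carrier_spec()) {
  stopifnot(inherits(mod, "modulation"), inherits(carrier, "carrier_spec"))
  if (mod$kind != "complex")
    stop_fibrescope("binarize_lee expects a complex modulation", "invalid_spec")
  f <- mod$field
  amax <- max(Mod(f))
  if (amax == 0) stop_fibrescope("cannot encode a zero field", "degenerate_input")
  q <- asin(pmin(Mod(f) / amax, 1)) / pi * (carrier$duty_max / 0.5)
  n1 <- nrow(f); n2 <- ncol(f)
  # carrier sampled at pixel centres (i - 1/2): keeps the grating free of the
  # exact cos() zero-crossing ties that arise at integer-pixel sampling
  i <- matrix(seq_len(n1) - 0.5, n1, n2)
  j <- matrix(rep(seq_len(n2) - 0.5, each = n1), n1, n2)
  carrier_phase <- 2 * pi * (carrier$freq[1] * i + carrier$freq[2] * j)
  pattern <- (cos(carrier_phase + Arg(f)) > cos(pi * q)) * 1
  modulation(pattern, kind = "binary", grid = mod$grid)
}

#' Decode the first diffraction order of a binary hologram
#'
#' Fourier-filters a disk around the carrier frequency, demodulates to
#' baseband and returns the complex field (the test-side inverse of
#' [binarize_lee()], up to an overall gain).
#'
#' @param pattern A binary [modulation()].
#' @param carrier The [carrier_spec()] used for encoding.
#' @param radius Filter radius in cycles/pixel; default 0.35 times the
#'   carrier magnitude (enough separation from the duty-cycle baseband and the
#'   higher grating harmonics).
#' @return A complex [modulation()].
#' @export
decode_first_order <- function(pattern, carrier = carrier_spec(),
                               radius = NULL) {
  stopifnot(inherits(pattern, "modulation"))
  if (is.null(radius)) radius <- 0.35 * carrier$magnitude
  f <- pattern$field
  n1 <- nrow(f); n2 <- ncol(f)
  sp <- fft2(f)
  f1 <- fft_freq(n1); f2 <- fft_freq(n2)
  d1 <- outer(wrap_freq_dist(f1, carrier$freq[1]), rep(1, n2))
  d2 <- outer(rep(1, n1), wrap_freq_dist(f2, carrier$freq[2]))
  sp[sqrt(d1^2 + d2^2) > radius] <- 0
  band <- ifft2(sp)
  i <- matrix(seq_len(n1) - 0.5, n1, n2)   # same pixel-centre convention as
  j <- matrix(rep(seq_len(n2) - 0.5, each = n1), n1, n2)  # binarize_lee
  base <- band * exp(-2i * pi * (carrier$freq[1] * i + carrier$freq[2] * j))
  modulation(base, kind = "complex", grid = pattern$grid)
}

# Distance on the periodic frequency axis (cycles/pixel) to a target
# frequency, accounting for aliasing wrap-around.
#' @noRd
wrap_freq_dist <- function(f, f0) {
  d <- (f - f0) %% 1
  pmin(d, 1 - d)
}
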