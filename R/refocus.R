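# Angular-spectrum propagation of transverse fields and transmission
# matrices to arbitrary axial planes, enabling volumetric scanning without
# recalibration.

#' Refocus specification
#'
#' @param z Signed refocus distance in micrometres; positive away from the
#'   distal facet, toward the tissue.
#' @param medium_index Refractive index of the propagation medium (default
#'   1.33, water-like brain tissue).
#' @param evanescent_policy What to do with spatial frequencies beyond the
#'   propagating band `|k_t| > k * n`: `"zero"` (default, stable for tens of
#'   micrometres) or `"error"`.
#' @param pad Integer zero-padding factor applied around the field before the
#'   transform. The default 1 (no padding) keeps propagation exactly unitary
#'   and invertible on the periodic grid; use 2 to suppress wrap-around for
#'   fields approaching the grid edge.
#' @return An object of class `refocus_spec`.
#' @export
refocus_spec <- function(z, medium_index = 1.33,
                         evanescent_policy = c("zero", "error"), pad = 1) {
  stopifnot(is_scalar_number(z), is_scalar_number(medium_index))
  if (medium_index < 1)
    stop_fibrescope("medium_index must be >= 1", "invalid_spec")
  structure(list(z = z, medium_index = medium_index,
                 evanescent_policy = match.arg(evanescent_policy),
                 pad = as.integer(pad)),
            class = "refocus_spec")
}

# Angular-spectrum transfer function exp(i z sqrt(k^2 n^2 - kx^2 - ky^2)) on
# the (possibly padded) grid; evanescent components per policy.
#' @noRd
asm_kernel <- function(n_pixels, pitch, wavelength, spec) {
  kn <- 2 * pi * spec$medium_index / wavelength
  kt <- 2 * pi * fft_freq(n_pixels) / pitch
  kx2 <- outer(kt^2, rep(1, n_pixels))
  ky2 <- t(kx2)
  arg <- kn^2 - kx2 - ky2
  evan <- arg < 0
  if (any(evan) && spec$evanescent_policy == "error" && spec$z != 0)
    stop_fibrescope("field band exceeds the propagating cone k*n",
                    "evanescent_error")
  h <- exp(1i * spec$z * sqrt(pmax(arg, 0)))
  h[evan] <- 0i
  h
}

#' Propagate a field by the angular-spectrum method
#'
#' Fourier-transforms the field to the angular spectrum, multiplies by the
#' exact spherical phase factor `exp(i z sqrt(k^2 n^2 - kx^2 - ky^2))` over
#' propagating components (evanescent ones handled per policy), and
#' transforms back. `z = 0` is the identity.
#'
#' @param field Complex field matrix.
#' @param grid The [field_grid()] of the field.
#' @param wavelength Vacuum wavelength in micrometres.
#' @param spec A [refocus_spec()].
#' @param fresnel Use the paraxial (Fresnel) kernel
#'   `exp(i z (k n - (kx^2 + ky^2) / (2 k n)))` instead of the exact one.
#' @return Complex field matrix at the new plane.
#' @export
propagate_field <- function(field, grid, wavelength, spec, fresnel = FALSE) {
  stopifnot(inherits(grid, "field_grid"), inherits(spec, "refocus_spec"))
  if (spec$z == 0) return(field)
  n <- grid$n_pixels
  np <- n * spec$pad
  f <- field
  if (spec$pad > 1) {
    fp <- matrix(0i, np, np)
    o <- floor((np - n) / 2)
    fp[o + seq_len(n), o + seq_len(n)] <- field
    f <- fp
  }
  if (fresnel) {
    kn <- 2 * pi * spec$medium_index / wavelength
    kt <- 2 * pi * fft_freq(np) / grid$pitch
    kx2 <- outer(kt^2, rep(1, np)); ky2 <- t(kx2)
    h <- exp(1i * spec$z * (kn - (kx2 + ky2) / (2 * kn)))
    h[kx2 + ky2 > kn^2] <- 0i
  } else {
    h <- asm_kernel(np, grid$pitch, wavelength, spec)
  }
  out <- ifft2(fft2(f) * h)
  if (spec$pad > 1) {
    o <- floor((np - n) / 2)
    out <- out[o + seq_len(n), o + seq_len(n)]
  }
  out
}

#' Refocus a transmission matrix to another axial plane
#'
#' Applies [propagate_field()] to the output field of every matrix column and
#' shifts the calibration plane bookkeeping by `z`. Kinoforms computed from
#' the result focus at the new plane, mirroring the instrument's ladder of
#' focal planes computed from a single calibration.
#'
#' @param tm A [transmission_matrix()].
#' @param spec A [refocus_spec()].
#' @return The refocused `transmission_matrix`, with `calibration_plane_z`
#'   advanced by `spec$z` and the parent matrix hash recorded in
#'   `attr(, "parent_hash")`.
#' @export
refocus_tm <- function(tm, spec) {
  stopifnot(inherits(tm, "transmission_matrix"), inherits(spec, "refocus_spec"))
  if (spec$z == 0) return(tm)
  n <- tm$output_grid$n_pixels
  np <- n * spec$pad
  m <- tm$matrix
  if (spec$pad == 1) {
    h <- asm_kernel(n, tm$output_grid$pitch, tm$wavelength, spec)
    for (j in seq_len(ncol(m)))
      m[, j] <- as.vector(ifft2(fft2(matrix(m[, j], n)) * h))
  } else {
    for (j in seq_len(ncol(m)))
      m[, j] <- as.vector(propagate_field(matrix(m[, j], n), tm$output_grid,
                                          tm$wavelength, spec))
  }
  out <- transmission_matrix(m, tm$output_grid, tm$input_basis,
                             calibration_plane_z = tm$calibration_plane_z + spec$z,
                             wavelength = tm$wavelength,
                             medium_index = spec$medium_index)
  attr(out, "parent_hash") <- object_hash(tm$matrix)
  attr(out, "refocus_z") <- spec$z
  out
}

#' Ladder of refocused transmission matrices
#'
#' @param tm The calibrated [transmission_matrix()].
#' @param offsets Numeric vector of refocus distances in micrometres (e.g.
#'   `seq(-10, 10, by = 2.5)` for the 9-plane ladder).
#' @param ... Passed to [refocus_spec()].
#' @return List of transmission matrices, one per offset, named by offset.
#' @export
refocus_ladder <- function(tm, offsets, ...) {
  out <- lapply(offsets, function(z) refocus_tm(tm, refocus_spec(z, ...)))
  names(out) <- format(offsets, trim = TRUE)
  out
}

#' Axial intensity profile of a field
#'
#' Propagates a field over a ladder of axial displacements and records the
#' on-axis maximum intensity at each plane; used to locate the axial position
#' of a focus.
#'
#' @param field Complex field matrix.
#' @param grid Its [field_grid()].
#' @param wavelength Vacuum wavelength (um).
#' @param z_values Axial displacements to probe (um).
#' @param medium_index Propagation medium index.
#' @return Data frame with columns `z` and `peak_intensity`.
#' @export
axial_profile <- function(field, grid, wavelength, z_values,
                          medium_index = 1.33) {
  peak <- vapply(z_values, function(z) {
    f <- propagate_field(field, grid, wavelength,
                         refocus_spec(z, medium_index = medium_index))
    max(Mod(f)^2)
  }, numeric(1))
  data.frame(z = z_values, peak_intensity = peak)
}
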