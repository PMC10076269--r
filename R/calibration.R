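# Simulated transmission-matrix acquisition by phase-shifting interferometry
# and focus synthesis with quality metrics.

#' Complex-field reconstruction from phase-shifted interferograms
#'
#' Solves, per pixel and in least squares, `I_k = |E + r exp(i theta_k)|^2`
#' for the unknown field `E` given intensity frames at known reference phase
#' steps. With the 4-step ladder `theta = {0, pi/2, pi, 3*pi/2}` and noiseless
#' frames the solution is exact to round-off.
#'
#' @param intensity_frames List of real matrices (or a matrix with one
#'   flattened frame per column), one per phase step.
#' @param reference Complex reference field (matrix or vector on the same
#'   grid). Pixels where the reference amplitude is zero are flagged invalid
#'   (`NA` in the output, indices in `attr(, "invalid")`).
#' @param phase_steps Numeric vector of reference phases in radians; at least
#'   3 steps, distinct modulo `2 pi`.
#' @return Complex array shaped like the input frames.
#' @export
psi_reconstruct <- function(intensity_frames,
                            reference,
                            phase_steps = seq(0, 3) * pi / 2) {
  if (is.list(intensity_frames)) {
    shape <- dim(intensity_frames[[1]])
    frames <- vapply(intensity_frames, as.vector,
                     numeric(length(intensity_frames[[1]])))
  } else {
    shape <- NULL
    frames <- intensity_frames
  }
  k <- ncol(frames)
  if (k < 3)
    stop_fibrescope("phase-shifting reconstruction needs >= 3 frames",
                    "invalid_spec")
  if (length(phase_steps) != k)
    stop_fibrescope("one phase step per frame required", "invalid_spec")
  if (any(duplicated(round(phase_steps %% (2 * pi), 12))))
    stop_fibrescope("phase steps must be distinct modulo 2*pi", "invalid_spec")
  r <- as.vector(reference)
  if (length(r) != nrow(frames))
    stop_fibrescope("reference and frames must share a grid", "invalid_spec")

  # I_k = c0 + 2 x cos(theta_k) + 2 y sin(theta_k), with x + i y = E conj(r)
  a <- cbind(1, 2 * cos(phase_steps), 2 * sin(phase_steps))
  p <- solve(crossprod(a), t(a))          # 3 x k pseudo-inverse
  coef <- frames %*% t(p)                 # n_pix x 3
  ec <- complex(real = coef[, 2], imaginary = coef[, 3])
  invalid <- which(Mod(r) == 0)
  e <- ec / Conj(r)
  e[invalid] <- NA_complex_
  out <- if (is.null(shape)) e else matrix(e, shape[1], shape[2])
  attr(out, "invalid") <- invalid
  out
}

#' Acquire a transmission matrix by simulated phase-shifting interferometry
#'
#' Sends every input-basis element through the forward operator, interferes
#' the output with the reference beam at each phase step, and reconstructs
#' the complex output field per element with [psi_reconstruct()]. Column `j`
#' of the result is the reconstructed output of basis element `j`.
#'
#' @param forward A [ground_truth_operator()].
#' @param basis An [make_input_basis()] result.
#' @param reference Complex reference field; default a uniform unit-amplitude
#'   plane wave.
#' @param phase_steps Reference phases in radians (default 4 equally spaced
#'   steps).
#' @param noise_sd Standard deviation of optional additive Gaussian intensity
#'   noise on the interferograms.
#' @param reference_phase_error Global phase actually present on the
#'   reference arm but unknown to the reconstruction; a nonzero value
#'   multiplies every matrix entry by `exp(-i * reference_phase_error)`.
#' @param calibration_plane_z Axial position of the calibration (camera)
#'   plane in micrometres (0 = distal facet).
#' @param medium_index Refractive index of the calibration medium.
#' @param seed Seed for the intensity noise.
#' @return An object of class `transmission_matrix`.
#' @export
acquire_tm <- function(forward, basis,
                       reference = NULL,
                       phase_steps = seq(0, 3) * pi / 2,
                       noise_sd = 0,
                       reference_phase_error = 0,
                       calibration_plane_z = 0,
                       medium_index = 1.33,
                       seed = 1) {
  stopifnot(inherits(forward, "forward_operator"))
  fields <- if (inherits(basis, "input_basis")) basis$fields else basis
  n_pix <- nrow(fields)
  if (is.null(reference)) reference <- rep(1 + 0i, n_pix)
  out <- apply_forward(forward, fields)

  r_actual <- as.vector(reference) * exp(1i * reference_phase_error)
  frames <- lapply(phase_steps, function(th)
    Mod(out + r_actual * exp(1i * th))^2)
  if (noise_sd > 0) {
    frames <- with_seed(seed, lapply(frames, function(fr)
      fr + matrix(stats::rnorm(length(fr), sd = noise_sd), nrow(fr))))
  }
  # reconstruct all columns at once: frames stacked column-blockwise
  frames <- do.call(cbind, lapply(frames, as.vector))
  r_rep <- rep(as.vector(reference), ncol(out))
  e <- psi_reconstruct(frames, r_rep, phase_steps)
  m <- matrix(e, n_pix, ncol(out))

  transmission_matrix(
    matrix = m,
    output_grid = forward$grid,
    input_basis = if (inherits(basis, "input_basis")) basis else NULL,
    calibration_plane_z = calibration_plane_z,
    wavelength = forward$spec$wavelength,
    medium_index = medium_index)
}

#' Transmission-matrix container
#'
#' @param matrix Complex matrix, output grid samples x input basis elements.
#' @param output_grid A [field_grid()].
#' @param input_basis The [make_input_basis()] used for acquisition.
#' @param calibration_plane_z Axial position of the calibrated plane (um,
#'   0 = distal facet); must be finite and `>= 0` at acquisition (refocusing
#'   may move it).
#' @param wavelength Vacuum wavelength (um).
#' @param medium_index Refractive index of the imaging medium.
#' @return An object of class `transmission_matrix`.
#' @export
transmission_matrix <- function(matrix, output_grid, input_basis,
                                calibration_plane_z = 0,
                                wavelength, medium_index = 1.33) {
  stopifnot(inherits(output_grid, "field_grid"))
  if (nrow(matrix) != output_grid$n_pixels^2)
    stop_fibrescope("matrix rows inconsistent with output grid", "invalid_spec")
  if (!is.null(input_basis) && ncol(matrix) != input_basis$n_elements)
    stop_fibrescope("matrix columns inconsistent with input basis",
                    "invalid_spec")
  structure(list(matrix = matrix, output_grid = output_grid,
                 input_basis = input_basis,
                 calibration_plane_z = calibration_plane_z,
                 wavelength = wavelength, medium_index = medium_index),
            class = "transmission_matrix")
}

#' @export
print.transmission_matrix <- function(x, ...) {
  cat(sprintf(
    "<transmission_matrix> %d outputs x %d inputs, plane z = %.3g um, lambda %g um\n",
    nrow(x$matrix), ncol(x$matrix), x$calibration_plane_z, x$wavelength))
  invisible(x)
}

#' Synthesise a focus through the calibrated fibre
#'
#' Pushes the phase-conjugation kinoform for the requested target through the
#' ground-truth forward operator and reports focus quality metrics.
#'
#' @param tm A [acquire_tm()] (possibly refocused) transmission matrix.
#' @param forward The [ground_truth_operator()].
#' @param target Output sample (linear index or `(row, col)`).
#' @return List with `field` (complex output matrix), `modulation` and
#'   `report` (a `focus_report`).
#' @export
synthesize_focus <- function(tm, forward, target) {
  mod <- phase_conjugate_kinoform(tm, target)
  field <- apply_forward(forward, mod$field)
  report <- focus_metrics(field, forward$grid, target = target)
  list(field = field, modulation = mod, report = report)
}

#' Focus quality metrics
#'
#' Azimuthally averages the intensity about the peak, locates the first
#' radial minimum (Rayleigh radius), and derives the enclosed-power ratio and
#' the enhancement over the mean background outside twice that radius.
#'
#' @param field Complex field matrix on `grid`.
#' @param grid The [field_grid()] of the field.
#' @param target Optionally, the requested target sample (for bookkeeping).
#' @param bin_width Radial sampling step in micrometres (default `pitch / 2`).
#' @param background_factor Background region is `r > background_factor *`
#'   Rayleigh radius (default 2).
#' @param upsample Band-limited (FFT zero-padding) upsampling factor applied
#'   before profiling; exact for NA-limited fields.
#' @return An object of class `focus_report` with `peak_position` (um),
#'   `peak_index`, `rayleigh_radius` (um, `NA` with a warning if the profile
#'   has no local minimum), `power_ratio`, `enhancement` and the radial
#'   `profile`.
#' @export
focus_metrics <- function(field, grid, target = NULL, bin_width = NULL,
                          background_factor = 2, upsample = 4L) {
  stopifnot(inherits(grid, "field_grid"))
  field <- as.matrix(field)
  if (all(Mod(field) == 0))
    stop_fibrescope("zero field has no focus", "degenerate_input")
  if (is.null(bin_width)) bin_width <- grid$pitch / 2
  n <- grid$n_pixels

  # The output field is band-limited by the fibre NA (well inside Nyquist on
  # any grid accepted by the mode solver), so FFT zero-padding interpolates
  # it exactly; measure the profile on the upsampled intensity.
  up <- as.integer(upsample)
  fine <- fft_upsample(field, up)
  intensity <- Mod(fine)^2
  nf <- n * up
  pitch_f <- grid$pitch / up
  axis_f <- grid$axis[1] + (seq_len(nf) - 1) * pitch_f
  grid_f <- structure(list(n_pixels = nf, pitch = pitch_f, axis = axis_f),
                      class = "field_grid")

  peak_idx <- which.max(intensity)
  pr <- (peak_idx - 1L) %% nf + 1L
  pc <- (peak_idx - 1L) %/% nf + 1L
  peak_pos <- c(axis_f[pr], axis_f[pc])

  xf <- matrix(axis_f, nf, nf)
  rr <- sqrt((xf - peak_pos[1])^2 + (t(xf) - peak_pos[2])^2)

  # Azimuthal average by sampling circles about the peak.
  r_max <- (n / 2 - 1) * grid$pitch - max(abs(peak_pos))
  radii <- seq(0, max(r_max, 3 * bin_width), by = bin_width)
  prof <- vapply(radii, function(r) {
    if (r == 0)
      return(bilinear_interp(intensity, grid_f, peak_pos[1], peak_pos[2]))
    n_theta <- max(16L, ceiling(2 * pi * r / pitch_f) * 2L)
    th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
    mean(bilinear_interp(intensity, grid_f,
                         peak_pos[1] + r * cos(th),
                         peak_pos[2] + r * sin(th)))
  }, numeric(1))

  # first local minimum of the azimuthally averaged profile
  rayleigh <- NA_real_
  nb <- length(prof)
  for (i in 2:(nb - 1)) {
    if (prof[i] <= prof[i - 1] && prof[i] < prof[i + 1]) {
      off <- parabolic_offset(prof[i - 1], prof[i], prof[i + 1])
      rayleigh <- radii[i] + off * bin_width
      break
    }
  }
  if (is.na(rayleigh)) {
    warning("no radial minimum within the grid; Rayleigh radius undefined")
    power_ratio <- NA_real_
    enhancement <- NA_real_
  } else {
    total <- sum(intensity)
    power_ratio <- sum(intensity[rr <= rayleigh]) / total
    bg <- intensity[rr > background_factor * rayleigh]
    enhancement <- if (length(bg) > 0 && mean(bg) > 0)
      max(intensity) / mean(bg) else Inf
  }
  structure(list(peak_position = peak_pos, peak_index = peak_idx,
                 target = target, rayleigh_radius = rayleigh,
                 power_ratio = power_ratio, enhancement = enhancement,
                 profile = data.frame(r = radii, intensity = prof)),
            class = "focus_report")
}

#' @export
print.focus_report <- function(x, ...) {
  cat(sprintf(
    "<focus_report> peak at (%.2f, %.2f) um, Rayleigh radius %.3g um, power ratio %.3g, enhancement %.3g\n",
    x$peak_position[1], x$peak_position[2], x$rayleigh_radius, x$power_ratio,
    x$enhancement))
  invisible(x)
}
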