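# Laser-scanning fluorescence imaging of synthetic 3-D scenes: raster
# frames, multi-plane z-stacks and line-scan (random access) trajectories.
# Collection is modelled as uniform: signal = sum over voxels of
# fluorophore density times excitation intensity.

#' Three-dimensional fluorophore-density scene
#'
#' @param density Non-negative 3-D array `[nx, ny, nz]` of fluorophore
#'   concentration (arbitrary units); a matrix is promoted to a single-plane
#'   scene.
#' @param voxel_size Voxel edge lengths in micrometres (length 3 or scalar).
#' @param origin Coordinates (um) of the centre of voxel `[1, 1, 1]` relative
#'   to the fibre axis / distal facet; default centres the scene laterally on
#'   the axis with its first plane at `z = origin_z`.
#' @param origin_z Axial position of the first scene plane when `origin` is
#'   derived automatically.
#' @param channel Optional channel label.
#' @return An object of class `scene`.
#' @export
scene <- function(density, voxel_size, origin = NULL, origin_z = 0,
                  channel = NULL) {
  if (is.matrix(density)) density <- array(density, c(dim(density), 1L))
  stopifnot(length(dim(density)) == 3L)
  if (any(density < 0))
    stop_fibrescope("scene density must be non-negative", "invalid_spec")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0))
    stop_fibrescope("voxel_size must be > 0", "invalid_spec")
  d <- dim(density)
  if (is.null(origin))
    origin <- c(-(d[1] - 1) / 2 * voxel_size[1],
                -(d[2] - 1) / 2 * voxel_size[2],
                origin_z)
  structure(list(density = density, voxel_size = voxel_size, origin = origin,
                 channel = channel),
            class = "scene")
}

#' @noRd
scene_axis <- function(sc, dim_idx) {
  sc$origin[dim_idx] + (seq_len(dim(sc$density)[dim_idx]) - 1) *
    sc$voxel_size[dim_idx]
}

#' Scan plan
#'
#' @param mode `"raster"` or `"line"`.
#' @param field_of_view `(width_x, height_y)` of the raster in micrometres.
#' @param pixel_pitch Scan-pixel pitch in micrometres.
#' @param plane_offsets Focal-plane positions (um from the distal facet),
#'   e.g. `25 + seq(-10, 10, by = 2.5)` for a 9-plane ladder.
#' @param rate Frame rate (raster, Hz) or line rate (line mode, Hz).
#' @param trajectory For line mode, an `n x 2` matrix of `(x, y)` focus
#'   positions in micrometres.
#' @return An object of class `scan_plan`.
#' @export
scan_plan <- function(mode = c("raster", "line"),
                      field_of_view = c(20, 20), pixel_pitch = 1,
                      plane_offsets = 0, rate = 1, trajectory = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(plane_offsets)))
    stop_fibrescope("plane offsets must be finite", "invalid_spec")
  if (mode == "line") {
    if (is.null(trajectory) || nrow(trajectory) == 0)
      stop_fibrescope("line mode needs a non-empty trajectory", "invalid_spec")
  }
  nx <- max(1L, round(field_of_view[1] / pixel_pitch))
  ny <- max(1L, round(field_of_view[2] / pixel_pitch))
  structure(list(mode = mode, field_of_view = field_of_view,
                 pixel_pitch = pixel_pitch, plane_offsets = plane_offsets,
                 rate = rate, trajectory = trajectory,
                 n_x = nx, n_y = ny),
            class = "scan_plan")
}

# Scan positions in um: raster grid centred on the fibre axis (row-major
# serpentine acquisition order recorded separately) or line trajectory.
#' @noRd
scan_positions <- function(plan) {
  if (plan$mode == "line") return(plan$trajectory)
  xs <- (seq_len(plan$n_x) - (plan$n_x + 1) / 2) * plan$pixel_pitch
  ys <- (seq_len(plan$n_y) - (plan$n_y + 1) / 2) * plan$pixel_pitch
  cbind(x = rep(xs, each = plan$n_y), y = rep(ys, times = plan$n_x))
}

#' @noRd
pick_plane_tm <- function(tm_ladder, offset, tol = 1e-6) {
  if (inherits(tm_ladder, "transmission_matrix")) tm_ladder <- list(tm_ladder)
  z <- vapply(tm_ladder, function(tm) tm$calibration_plane_z, numeric(1))
  i <- which(abs(z - offset) < tol)
  if (length(i) == 0)
    stop_fibrescope(sprintf("no transmission matrix for plane offset %g um",
                            offset), "missing_plane")
  tm_ladder[[i[1]]]
}

# Batch focus synthesis: unit-power kinoform fields for each target position,
# pushed through the forward operator. Returns n_pix x n_pos output fields.
#' @noRd
batch_foci <- function(tm, forward, positions) {
  g <- tm$output_grid
  ix <- pmin(pmax(round(positions[, 1] / g$pitch + (g$n_pixels + 1) / 2), 1),
             g$n_pixels)
  iy <- pmin(pmax(round(positions[, 2] / g$pitch + (g$n_pixels + 1) / 2), 1),
             g$n_pixels)
  idx <- (iy - 1L) * g$n_pixels + ix
  kappa <- Conj(t(tm$matrix[idx, , drop = FALSE]))     # n_in x n_pos
  fields <- tm$input_basis$fields %*% kappa            # modulation fields
  pw <- colSums(Mod(fields)^2) * g$pitch^2
  fields <- sweep(fields, 2, sqrt(pw), `/`)
  apply_forward(forward, fields)
}

# Bilinear interpolation of a grid image at query points (um); zero outside.
#' @noRd
bilinear_interp <- function(img, grid, xq, yq) {
  n <- grid$n_pixels
  fx <- (xq - grid$axis[1]) / grid$pitch + 1
  fy <- (yq - grid$axis[1]) / grid$pitch + 1
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  val <- numeric(length(xq))
  ok <- i0 >= 1 & i0 <= n - 1 & j0 >= 1 & j0 <= n - 1
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; txk <- tx[ok]; tyk <- ty[ok]
    v00 <- img[cbind(i0k, j0k)];     v10 <- img[cbind(i0k + 1, j0k)]
    v01 <- img[cbind(i0k, j0k + 1)]; v11 <- img[cbind(i0k + 1, j0k + 1)]
    val[ok] <- v00 * (1 - txk) * (1 - tyk) + v10 * txk * (1 - tyk) +
      v01 * (1 - txk) * tyk + v11 * txk * tyk
  }
  val
}

# Excitation-overlap signal for a set of focus fields against a scene:
# propagates each focus through the scene depth and integrates
# density x |E|^2. Returns one signal per focus.
#' @noRd
overlap_signal <- function(out_fields, grid, wavelength, medium_index,
                           plane_z, sc, drift_xy = c(0, 0)) {
  n <- grid$n_pixels
  n_pos <- ncol(out_fields)
  zs <- scene_axis(sc, 3)
  xs <- scene_axis(sc, 1) + drift_xy[1]
  ys <- scene_axis(sc, 2) + drift_xy[2]
  qx <- rep(xs, times = length(ys))
  qy <- rep(ys, each = length(xs))
  signal <- numeric(n_pos)
  for (iz in seq_along(zs)) {
    dz <- zs[iz] - plane_z
    dens <- as.vector(sc$density[, , iz])
    if (all(dens == 0)) next
    for (p in seq_len(n_pos)) {
      fld <- matrix(out_fields[, p], n)
      if (dz != 0)
        fld <- propagate_field(fld, grid, wavelength,
                               refocus_spec(dz, medium_index = medium_index))
      iv <- bilinear_interp(Mod(fld)^2, grid, qx, qy)
      signal[p] <- signal[p] + sum(dens * iv)
    }
  }
  signal * prod(sc$voxel_size)
}

#' @noRd
apply_detector <- function(signal, noise_seed, photons_per_unit, full_well) {
  if (!is.null(noise_seed))
    signal <- with_seed(noise_seed,
                        stats::rpois(length(signal),
                                     signal * photons_per_unit) /
                          photons_per_unit)
  pmin(signal, full_well)
}

#' Raster-scan a single frame
#'
#' Synthesises a diffraction-limited focus at every raster position from the
#' transmission matrix of the requested focal plane, pushes it through the
#' ground-truth operator, propagates it through the scene depth and records
#' the excitation-density overlap as the detected signal. Optional Poisson
#' shot noise and a detector full-well clip model the photodetector.
#'
#' @param tm_ladder A single [transmission_matrix()] or a list of refocused
#'   ones, matched to `plan$plane_offsets` by their `calibration_plane_z`.
#' @param forward The [ground_truth_operator()].
#' @param scene A [scene()].
#' @param plan A raster [scan_plan()].
#' @param noise_seed Seed for Poisson shot noise; `NULL` (default) disables
#'   noise.
#' @param plane Index into `plan$plane_offsets` to image.
#' @param photons_per_unit Photon count per unit of noiseless signal (shot
#'   noise scaling).
#' @param full_well Detector saturation level in signal units.
#' @return A `scan_frame`: matrix `n_y x n_x` with attributes `plane_offset`,
#'   `plan` and `timestamp`.
#' @export
scan_frame <- function(tm_ladder, forward, scene, plan, noise_seed = NULL,
                       plane = 1L, photons_per_unit = 100, full_well = Inf,
                       timestamp = 0) {
  stopifnot(inherits(plan, "scan_plan"), inherits(scene, "scene"))
  if (plan$mode != "raster")
    stop_fibrescope("scan_frame needs a raster plan", "invalid_spec")
  offset <- plan$plane_offsets[plane]
  tm <- pick_plane_tm(tm_ladder, offset)
  pos <- scan_positions(plan)
  out <- batch_foci(tm, forward, pos)
  sig <- overlap_signal(out, tm$output_grid, tm$wavelength, tm$medium_index,
                        tm$calibration_plane_z, scene)
  sig <- apply_detector(sig, noise_seed, photons_per_unit, full_well)
  frame <- matrix(sig, plan$n_y, plan$n_x)   # positions are y-fast
  structure(frame, plane_offset = offset, plan = plan, timestamp = timestamp,
            class = c("scan_frame", "matrix"))
}

#' Acquire a z-stack of raster frames
#'
#' One frame per entry of `plan$plane_offsets`, in plan order, sharing a
#' timestamp base.
#'
#' @inheritParams scan_frame
#' @param timestamp Acquisition time of the stack (s).
#' @return A `zstack`: list of `scan_frame`s ordered as the plan's offsets.
#' @export
scan_zstack <- function(tm_ladder, forward, scene, plan, noise_seed = NULL,
                        photons_per_unit = 100, full_well = Inf,
                        timestamp = 0) {
  frames <- lapply(seq_along(plan$plane_offsets), function(i)
    scan_frame(tm_ladder, forward, scene, plan,
               noise_seed = if (is.null(noise_seed)) NULL
                            else noise_seed + i,
               plane = i, photons_per_unit = photons_per_unit,
               full_well = full_well, timestamp = timestamp))
  structure(frames, plan = plan, timestamp = timestamp, class = "zstack")
}

#' Line-scan a trajectory into a kymograph
#'
#' Repeatedly scans the plan's trajectory; each sweep forms one column of the
#' record (one row per trajectory point). The scene may drift at constant
#' velocity to emulate moving structures.
#'
#' @inheritParams scan_frame
#' @param plan A line-mode [scan_plan()] (its `rate` is the line rate in Hz).
#' @param n_sweeps Number of line sweeps (columns).
#' @param drift Scene drift velocity `(vx, vy)` in um/s.
#' @return A [kymograph()] (rows = trajectory points, columns = sweeps).
#' @export
scan_line <- function(tm_ladder, forward, scene, plan, n_sweeps,
                      drift = c(0, 0), noise_seed = NULL,
                      photons_per_unit = 100, full_well = Inf) {
  stopifnot(inherits(plan, "scan_plan"))
  if (plan$mode != "line")
    stop_fibrescope("scan_line needs a line plan", "invalid_spec")
  tm <- pick_plane_tm(tm_ladder, plan$plane_offsets[1])
  pos <- scan_positions(plan)
  out <- batch_foci(tm, forward, pos)
  n_traj <- nrow(pos)
  data <- matrix(0, n_traj, n_sweeps)
  static <- all(drift == 0)
  sig0 <- overlap_signal(out, tm$output_grid, tm$wavelength, tm$medium_index,
                         tm$calibration_plane_z, scene)
  for (s in seq_len(n_sweeps)) {
    if (static) {
      data[, s] <- sig0
    } else {
      t_s <- (s - 1) / plan$rate
      data[, s] <- overlap_signal(out, tm$output_grid, tm$wavelength,
                                  tm$medium_index, tm$calibration_plane_z,
                                  scene, drift_xy = drift * t_s)
    }
  }
  if (!is.null(noise_seed))
    data <- with_seed(noise_seed,
                      matrix(stats::rpois(length(data),
                                          data * photons_per_unit) /
                               photons_per_unit, n_traj))
  data <- pmin(data, full_well)
  step <- sqrt(rowSums(diff(pos)^2))
  kymograph(data, line_rate = plan$rate,
            pixel_pitch = if (n_traj > 1) mean(step) else plan$pixel_pitch)
}

#' Background-subtracted ROI traces from line records
#'
#' For simultaneously recorded line-scan kymographs, returns per-sweep traces
#' `mean(ROI_i) - mean(background)`, mirroring calcium-activity line imaging
#' with a dedicated background trajectory.
#'
#' @param records List of [kymograph()]s with equal sweep counts (at least
#'   one ROI plus the background record).
#' @param background_index Index of the background record within `records`.
#' @return Data frame with time `t` (s, from the first record's line rate)
#'   and one column per ROI, in input order.
#' @export
roi_traces <- function(records, background_index) {
  if (length(records) < 2)
    stop_fibrescope("need at least one ROI and one background record",
                    "invalid_spec")
  ns <- vapply(records, function(k) ncol(k$data), integer(1))
  if (length(unique(ns)) != 1)
    stop_fibrescope("sweep-count mismatch across records", "invalid_spec")
  bg <- colMeans(records[[background_index]]$data)
  rois <- setdiff(seq_along(records), background_index)
  out <- data.frame(t = (seq_len(ns[1]) - 1) / records[[1]]$line_rate)
  for (i in rois)
    out[[paste0("roi", i)]] <- colMeans(records[[i]]$data) - bg
  out
}
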