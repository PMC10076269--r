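# Seeded synthetic-data generators: fluorophore scenes (beads, neurons,
# vessels), red-blood-cell line-scan kymographs with modulated flow, and
# constant-drift scan records. Every generator is deterministic under a
# fixed seed and returns its ground truth alongside the data.

#' Phantom specification
#'
#' @param kind One of `"beads"`, `"neurons"`, `"vessels"`.
#' @param ... Kind-specific geometry parameters (see [make_scene()]).
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_level Poisson photon scale or Gaussian standard deviation.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind, ..., noise = c("none", "poisson", "gaussian"),
                         noise_level = 0, seed = 1) {
  kinds <- c("beads", "neurons", "vessels")
  if (!kind %in% kinds)
    stop_fibrescope(sprintf("unknown phantom kind '%s'", kind), "invalid_spec")
  structure(list(kind = kind, params = list(...), noise = match.arg(noise),
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @noRd
apply_scene_noise <- function(density, spec) {
  if (spec$noise == "none" || spec$noise_level <= 0) return(density)
  with_seed(spec$seed + 1L, {
    if (spec$noise == "poisson") {
      array(stats::rpois(length(density), density * spec$noise_level) /
              spec$noise_level, dim(density))
    } else {
      pmax(density + array(stats::rnorm(length(density),
                                        sd = spec$noise_level),
                           dim(density)), 0)
    }
  })
}

#' Generate a synthetic fluorophore scene
#'
#' Kinds: `beads` places isolated sub-resolution points (for PSF tests);
#' `neurons` draws somata (5-15 um ellipsoids) with ~1 um dendrite tubes
#' carrying spine bumps; `vessels` draws 3-10 um tubes with an optional
#' hollow-wall variant (wall labelled, lumen dark). The background is exactly
#' zero; structures are positive.
#'
#' @param spec A [phantom_spec()].
#' @param dims Scene dimensions in voxels `(nx, ny, nz)`.
#' @param voxel_size Voxel size in um (scalar or length 3).
#' @param origin_z Axial position of the first plane (um).
#' @return A [scene()] with the generator's ground truth (bead positions,
#'   centrelines) in `attr(, "ground_truth")`.
#' @export
make_scene <- function(spec, dims = c(64, 64, 1), voxel_size = 0.5,
                       origin_z = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  p <- spec$params
  density <- array(0, dims)
  truth <- NULL
  ax <- lapply(1:3, function(d) (seq_len(dims[d]) - 1) * voxel_size[d])

  if (spec$kind == "beads") {
    n_beads <- p$n_beads %||% 1L
    positions <- p$positions
    if (is.null(positions)) {
      positions <- with_seed(spec$seed, cbind(
        stats::runif(n_beads, 0.2, 0.8) * (dims[1] - 1) * voxel_size[1],
        stats::runif(n_beads, 0.2, 0.8) * (dims[2] - 1) * voxel_size[2],
        stats::runif(n_beads, 0, 1) * (dims[3] - 1) * voxel_size[3]))
    }
    amp <- p$amplitude %||% 1
    for (b in seq_len(nrow(positions))) {
      idx <- vapply(1:3, function(d)
        which.min(abs(ax[[d]] - positions[b, d])), integer(1))
      density[idx[1], idx[2], idx[3]] <- density[idx[1], idx[2], idx[3]] + amp
    }
    truth <- list(positions = positions)
  } else if (spec$kind == "neurons") {
    n_cells <- p$n_cells %||% 3L
    truth <- with_seed(spec$seed, {
      somata <- cbind(
        stats::runif(n_cells, 0.15, 0.85) * max(ax[[1]]),
        stats::runif(n_cells, 0.15, 0.85) * max(ax[[2]]),
        stats::runif(n_cells, 0, 1) * max(ax[[3]], 0))
      radii <- stats::runif(n_cells, 2.5, 7.5)   # 5-15 um somata
      angles <- stats::runif(n_cells, 0, 2 * pi)
      list(somata = somata, radii = radii, angles = angles)
    })
    co <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    for (cidx in seq_len(n_cells)) {
      s <- truth$somata[cidx, ]; r0 <- truth$radii[cidx]
      d2 <- ((co$x - s[1]) / r0)^2 + ((co$y - s[2]) / r0)^2 +
        ((co$z - s[3]) / (0.7 * r0))^2
      density <- density + array(as.numeric(d2 <= 1), dims)
      # one dendrite tube (~1 um) leaving the soma, with spine bumps
      dir <- c(cos(truth$angles[cidx]), sin(truth$angles[cidx]), 0)
      tl <- ((co$x - s[1]) * dir[1] + (co$y - s[2]) * dir[2])
      perp2 <- (co$x - s[1] - tl * dir[1])^2 + (co$y - s[2] - tl * dir[2])^2 +
        (co$z - s[3])^2
      tube <- tl > r0 & tl < r0 + (p$dendrite_length %||% 15) & perp2 <= 0.5^2
      spines <- tube & (sin(tl * 2 * pi / 3) > 0.95)   # bumps every ~3 um
      density <- density + array(0.6 * tube + 0.6 * spines, dims)
    }
  } else if (spec$kind == "vessels") {
    n_vessels <- p$n_vessels %||% 2L
    hollow <- isTRUE(p$hollow)
    truth <- with_seed(spec$seed, {
      y0 <- stats::runif(n_vessels, 0.2, 0.8) * max(ax[[2]])
      z0 <- stats::runif(n_vessels, 0, 1) * max(ax[[3]], 0)
      radii <- stats::runif(n_vessels, 1.5, 5)  # 3-10 um diameter
      list(y = y0, z = z0, radii = radii, hollow = hollow)
    })
    co <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    for (v in seq_len(n_vessels)) {
      d2 <- (co$y - truth$y[v])^2 + (co$z - truth$z[v])^2
      r <- truth$radii[v]
      if (hollow) {
        inside <- d2 <= r^2 & d2 >= (0.7 * r)^2
      } else {
        inside <- d2 <= r^2
      }
      density <- density + array(as.numeric(inside), dims)
    }
  }
  density <- apply_scene_noise(density, spec)
  sc <- scene(density, voxel_size, origin_z = origin_z,
              channel = spec$params$channel)
  attr(sc, "ground_truth") <- truth
  sc
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic red-blood-cell kymograph with known velocity
#'
#' Streaks advance per the integrated velocity profile; optional dark-on-
#' bright contrast emulates unlabelled cells in fluorescent plasma,
#' per-row multiplicative gains emulate the row-to-row variation of the
#' fluorescence response, and Poisson or Gaussian noise is applied last.
#'
#' @param v_profile Velocity in px/line: a constant, a vector (one value per
#'   line) or a function of time in seconds.
#' @param n_lines Number of line scans (columns); `>= 2`.
#' @param n_pixels Pixels per line (rows).
#' @param line_rate Line rate in Hz.
#' @param pixel_pitch Pixel pitch in um.
#' @param streak_density Mean number of cells present per line.
#' @param streak_width Gaussian 1-sigma streak width in px.
#' @param dark_cells Dark streaks on a bright plasma background instead of
#'   bright streaks on dark background.
#' @param row_gains `NULL` (unit gains), a numeric vector, or `"random"` for
#'   seeded gains in `[0.5, 2]`.
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_level Photon scale (Poisson; larger = cleaner) or standard
#'   deviation (Gaussian).
#' @param seed Integer seed.
#' @return A [kymograph()] with `attr(, "v_true")`, the requested velocity
#'   sampled per column (px/line).
#' @export
make_rbc_kymograph <- function(v_profile, n_lines = 500, n_pixels = 64,
                               line_rate = 1000, pixel_pitch = 0.5,
                               streak_density = 4, streak_width = 2,
                               dark_cells = FALSE, row_gains = NULL,
                               noise = c("none", "poisson", "gaussian"),
                               noise_level = 0, seed = 1) {
  noise <- match.arg(noise)
  if (n_lines < 2)
    stop_fibrescope("n_lines must be >= 2", "invalid_spec")
  t_axis <- (seq_len(n_lines) - 1) / line_rate
  v <- if (is.function(v_profile)) v_profile(t_axis)
       else if (length(v_profile) == 1) rep(v_profile, n_lines)
       else v_profile
  if (length(v) != n_lines)
    stop_fibrescope("v_profile must yield one velocity per line",
                    "invalid_spec")
  disp <- c(0, cumsum(v[-n_lines]))  # displacement at each column (px)

  data <- with_seed(seed, {
    # enough cells that the field stays populated while flowing through
    travel <- max(abs(disp)) + n_pixels
    n_cells <- max(1L, stats::rpois(1, streak_density * travel / n_pixels))
    r0 <- stats::runif(n_cells, -travel, n_pixels + travel)
    amp <- stats::runif(n_cells, 0.7, 1.3)
    rows <- seq_len(n_pixels)
    d <- matrix(0, n_pixels, n_lines)
    for (ci in seq_len(n_cells)) {
      centre <- r0[ci] + disp
      # wrap cells around so streaks keep entering the field
      centre <- ((centre + travel) %% (n_pixels + 2 * travel)) - travel
      for (col in seq_len(n_lines)) {
        dr <- rows - centre[col]
        near <- abs(dr) < 4 * streak_width
        if (any(near))
          d[near, col] <- d[near, col] +
            amp[ci] * exp(-dr[near]^2 / (2 * streak_width^2))
      }
    }
    d
  })
  if (dark_cells) data <- pmax(1.5 - data, 0)
  if (identical(row_gains, "random"))
    row_gains <- with_seed(seed + 1L, stats::runif(n_pixels, 0.5, 2))
  if (!is.null(row_gains)) data <- data * row_gains
  if (noise != "none" && noise_level > 0) {
    data <- with_seed(seed + 2L, {
      if (noise == "poisson")
        matrix(stats::rpois(length(data), data * noise_level) / noise_level,
               n_pixels)
      else
        data + matrix(stats::rnorm(length(data), sd = noise_level), n_pixels)
    })
  }
  k <- kymograph(data, line_rate, pixel_pitch)
  attr(k, "v_true") <- v
  k
}

#' Constant-drift scan record of a scene
#'
#' Emulates the probe advancing through the tissue at constant speed while
#' z-stacks are scanned at a fixed rate: stack `k` images the scene window
#' displaced by `k * speed / frame_rate` micrometres along the insertion
#' (row) axis. Imaging uses direct scene sampling (ideal delta-like
#' excitation) by default; pass a transmission-matrix setup via `imaging`
#' for full synthesis.
#'
#' @param scene A [scene()]; must extend beyond the field of view along the
#'   drift axis.
#' @param speed Probe insertion speed in um/s.
#' @param plan A raster [scan_plan()] defining the frame shape (its
#'   `plane_offsets` select the scene planes by index up to the available
#'   depth).
#' @param frame_rate Stack rate in Hz (the default 0.3 Hz with
#'   1 um/s insertion gives a 3.33 um inter-stack shift).
#' @param n_stacks Number of stacks.
#' @param seed Seed for the optional Poisson noise.
#' @param noise_level Photon scale; 0 disables noise.
#' @param imaging `"ideal"` (sample the density directly) or a list
#'   `list(tm_ladder =, forward =)` for full focus-synthesis imaging.
#' @return A [scan_record()] with `attr(, "ground_truth")` holding the scene
#'   and the per-stack row offsets in pixels.
#' @export
make_drift_record <- function(scene, speed, plan, frame_rate = 0.3,
                              n_stacks = 10, seed = 1, noise_level = 0,
                              imaging = "ideal") {
  stopifnot(inherits(scene, "scene"), inherits(plan, "scan_plan"))
  shift_um <- speed / frame_rate
  n_rows <- plan$n_y
  d <- dim(scene$density)
  px_shift <- shift_um / scene$voxel_size[2]
  if (px_shift > n_rows)
    stop_fibrescope("drift per stack exceeds the frame extent: no overlap",
                    "invalid_spec")
  total_rows <- round((n_stacks - 1) * px_shift) + n_rows
  if (d[2] < total_rows)
    stop_fibrescope("scene too short along the drift axis for this record",
                    "invalid_spec")
  n_planes <- length(plan$plane_offsets)
  stacks <- vector("list", n_stacks)
  offsets <- numeric(n_stacks)
  for (k in seq_len(n_stacks)) {
    off <- (k - 1) * px_shift
    offsets[k] <- off
    frames <- vector("list", n_planes)
    for (p in seq_len(n_planes)) {
      iz <- min(p, d[3])
      if (identical(imaging, "ideal")) {
        fr <- sample_scene_window(scene, off, n_rows, plan$n_x, iz)
      } else {
        fr <- scan_frame(imaging$tm_ladder, imaging$forward,
                         shift_scene(scene, -off * scene$voxel_size[2]),
                         plan, plane = p)
        fr <- as.matrix(fr)
      }
      if (noise_level > 0)
        fr <- with_seed(seed + 13L * k + p,
                        matrix(stats::rpois(length(fr), fr * noise_level) /
                                 noise_level, nrow(fr)))
      frames[[p]] <- fr
    }
    stacks[[k]] <- frames
  }
  rec <- scan_record(stacks, frame_rate, insertion_speed = speed)
  attr(rec, "ground_truth") <- list(scene = scene,
                                    offsets_px = offsets,
                                    speed_px_per_frame = px_shift)
  rec
}

# Sample an n_rows x n_cols window of a scene plane starting at fractional
# row offset `off` (linear interpolation along the drift axis).
#' @noRd
sample_scene_window <- function(sc, off, n_rows, n_cols, iz) {
  d <- dim(sc$density)
  rows <- seq_len(n_rows) + off
  i0 <- floor(rows); tfrac <- rows - i0
  i0 <- pmin(pmax(i0, 1L), d[2] - 1L)
  plane <- sc$density[, , iz]
  cols <- seq_len(min(n_cols, d[1]))
  w <- t(plane[cols, i0] * rep(1 - tfrac, each = length(cols)) +
           plane[cols, i0 + 1L] * rep(tfrac, each = length(cols)))
  if (n_cols > d[1])
    w <- cbind(w, matrix(0, n_rows, n_cols - d[1]))
  w
}

#' @noRd
shift_scene <- function(sc, dy_um) {
  sc$origin[2] <- sc$origin[2] + dy_um
  sc
}
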