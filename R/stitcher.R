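# Whole-depth stitching of z-stack records acquired while the probe advances
# through the tissue: per-scan contrast floor subtraction, overlap-based
# speed estimation and 4-D (space x time) to 3-D assembly with averaging.

#' Time series of z-stacks from a moving probe
#'
#' @param stacks Time-ordered list of `zstack`s (or of plain frame lists /
#'   matrices for single-plane records) sharing one plan.
#' @param frame_rate Stack rate in Hz.
#' @param insertion_speed Nominal probe insertion speed in um/s (metadata).
#' @param probe_geometry `"straight"` or `"side"`.
#' @param skip_leading Leading stacks to exclude from speed estimation and
#'   stitching (non-uniform entry phase, e.g. dura perforation).
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(stacks, frame_rate, insertion_speed = NA_real_,
                        probe_geometry = c("side", "straight"),
                        skip_leading = 0L) {
  if (length(stacks) < 2)
    stop_fibrescope("stitching needs at least 2 stacks", "invalid_spec")
  stacks <- lapply(stacks, function(s) {
    if (is.matrix(s)) list(s) else s
  })
  np <- vapply(stacks, length, integer(1))
  if (length(unique(np)) != 1)
    stop_fibrescope("all stacks must share a plan (plane count differs)",
                    "invalid_spec")
  structure(list(stacks = stacks, frame_rate = frame_rate,
                 insertion_speed = insertion_speed,
                 probe_geometry = match.arg(probe_geometry),
                 skip_leading = as.integer(skip_leading)),
            class = "scan_record")
}

#' Contrast floor subtraction
#'
#' Subtracts the mean of the lowest `ceiling(fraction * N)` intensity pixels
#' of a scan and clamps negative results to zero; with the default 1%
#' fraction this is the per-scan contrast enhancement used before stitching
#' whole-depth records. Applied to a `scan_record`, every frame is processed.
#'
#' @param x A frame (matrix) or a [scan_record()].
#' @param fraction Fraction of lowest-intensity pixels defining the floor,
#'   in `(0, 1)`.
#' @return The floor-subtracted object, same shape as the input.
#' @export
floor_subtract <- function(x, fraction = 0.01) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1)
    stop_fibrescope("fraction must lie in (0, 1)", "invalid_spec")
  if (inherits(x, "scan_record")) {
    x$stacks <- lapply(x$stacks, function(st)
      lapply(st, floor_subtract, fraction = fraction))
    return(x)
  }
  v <- as.vector(x)
  if (length(v) == 0)
    stop_fibrescope("empty frame", "degenerate_input")
  n_low <- ceiling(fraction * length(v))
  floor_val <- mean(sort(v, partial = n_low)[seq_len(n_low)])
  out <- pmax(x - floor_val, 0)
  attributes(out) <- attributes(x)
  out
}

#' Sub-pixel translation between overlapping frames
#'
#' Finds the integer shift along the insertion axis (rows) maximising the
#' normalised cross-correlation of the overlapping regions, then refines it
#' with a parabola through the peak and its two neighbours. The convention is
#' `frame_b[r] = frame_a[r + shift]` for positive shifts (tissue advancing
#' towards lower rows of successive frames).
#'
#' @param frame_a,frame_b Equal-shaped matrices.
#' @param search_range Maximum |shift| in pixels; capped so that the overlap
#'   keeps at least 25% of the frame.
#' @return Sub-pixel shift in pixels, with the correlation curve in
#'   `attr(, "ncc")`.
#' @export
estimate_shift <- function(frame_a, frame_b, search_range = NULL) {
  a <- as.matrix(frame_a); b <- as.matrix(frame_b)
  if (!all(dim(a) == dim(b)))
    stop_fibrescope("frames must have equal shapes", "invalid_spec")
  n <- nrow(a)
  max_s <- floor(0.75 * n)
  if (is.null(search_range)) search_range <- max_s
  search_range <- min(search_range, max_s)
  shifts <- seq(-search_range, search_range)
  ncc <- vapply(shifts, function(s) {
    if (s >= 0) {
      av <- a[(1 + s):n, , drop = FALSE]; bv <- b[1:(n - s), , drop = FALSE]
    } else {
      av <- a[1:(n + s), , drop = FALSE]; bv <- b[(1 - s):n, , drop = FALSE]
    }
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
    stats::cor(as.vector(av), as.vector(bv))
  }, numeric(1))
  if (all(is.na(ncc)))
    stop_fibrescope("flat overlap: shift undefined", "degenerate_input")
  i <- which.max(ncc)
  shift <- shifts[i]
  if (i > 1 && i < length(shifts) && !is.na(ncc[i - 1]) && !is.na(ncc[i + 1]))
    shift <- shift + parabolic_offset(-ncc[i - 1], -ncc[i], -ncc[i + 1])
  attr(shift, "ncc") <- data.frame(shift = shifts, ncc = ncc)
  shift
}

#' Probe speed from a drifting record
#'
#' Estimates the shift between every pair of neighbouring stacks (matched
#' planes averaged) and returns the mean in pixel-per-frame units, relying on
#' the uniform-velocity assumption of a constant-speed insertion.
#'
#' @param record A [scan_record()] with at least 3 stacks.
#' @param search_range Passed to [estimate_shift()].
#' @return Scalar speed in px/frame; per-pair estimates in
#'   `attr(, "pair_shifts")`.
#' @export
estimate_speed <- function(record, search_range = NULL) {
  stopifnot(inherits(record, "scan_record"))
  stacks <- record$stacks
  if (record$skip_leading > 0)
    stacks <- stacks[-seq_len(record$skip_leading)]
  if (length(stacks) < 3)
    stop_fibrescope("speed estimation needs >= 3 stacks", "invalid_spec")
  n_planes <- length(stacks[[1]])
  pair_shift <- rep(NA_real_, length(stacks) - 1)
  for (i in seq_len(length(stacks) - 1)) {
    per_plane <- vapply(seq_len(n_planes), function(p) {
      tryCatch(as.numeric(estimate_shift(stacks[[i]][[p]],
                                         stacks[[i + 1]][[p]],
                                         search_range)),
               fibrescope_error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(per_plane))) {
      warning(sprintf("stack pair %d-%d excluded: shift undefined", i, i + 1))
    } else {
      pair_shift[i] <- mean(per_plane, na.rm = TRUE)
    }
  }
  if (all(is.na(pair_shift)))
    stop_fibrescope("no stack pair yields a defined shift", "degenerate_input")
  speed <- mean(pair_shift, na.rm = TRUE)
  attr(speed, "pair_shifts") <- pair_shift
  speed
}

#' Stitch a drifting record into an extended volume
#'
#' Maps every pixel of every frame to the global coordinate
#' `frame_index * speed + local row` (nearest-voxel binning) and averages
#' voxels measured more than once.
#'
#' @param record A [scan_record()].
#' @param speed Probe speed in px/frame (e.g. from [estimate_speed()]);
#'   must be `> 0`.
#' @param voxel_size Optional voxel edge lengths (um) recorded as metadata.
#' @return An object of class `stitched_volume`: `volume` (array planes x
#'   global rows x columns), `count` (per-voxel sample count) and
#'   `voxel_size`.
#' @export
stitch <- function(record, speed, voxel_size = c(NA_real_, NA_real_, NA_real_)) {
  stopifnot(inherits(record, "scan_record"))
  if (!is_scalar_number(speed) || speed <= 0)
    stop_fibrescope("speed must be > 0", "invalid_spec")
  stacks <- record$stacks
  if (record$skip_leading > 0)
    stacks <- stacks[-seq_len(record$skip_leading)]
  n_planes <- length(stacks[[1]])
  n_rows <- nrow(stacks[[1]][[1]])
  n_cols <- ncol(stacks[[1]][[1]])
  n_stacks <- length(stacks)
  n_global <- round((n_stacks - 1) * speed) + n_rows
  vol <- array(0, c(n_planes, n_global, n_cols))
  cnt <- array(0L, c(n_planes, n_global, n_cols))
  for (k in seq_len(n_stacks)) {
    g <- round((k - 1) * speed) + seq_len(n_rows)
    keep <- g >= 1 & g <= n_global
    for (p in seq_len(n_planes)) {
      fr <- as.matrix(stacks[[k]][[p]])
      vol[p, g[keep], ] <- vol[p, g[keep], ] + fr[keep, ]
      cnt[p, g[keep], ] <- cnt[p, g[keep], ] + 1L
    }
  }
  measured <- cnt > 0
  vol[measured] <- vol[measured] / cnt[measured]
  structure(list(volume = vol, count = cnt, voxel_size = voxel_size,
                 speed = speed),
            class = "stitched_volume")
}

#' @export
print.stitched_volume <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf(
    "<stitched_volume> %d planes x %d rows x %d cols, speed %.3g px/frame\n",
    d[1], d[2], d[3], x$speed))
  invisible(x)
}
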