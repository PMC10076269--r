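# Blood-flow velocity estimation from line-scan kymographs by column
# morphing: candidate velocities shift neighbouring columns vertically to
# counteract cell motion; the mean row-wise standard deviation of the morphed
# window is minimised, with parabolic sub-step refinement.

#' Line-scan kymograph container
#'
#' @param data Real matrix; rows are pixels along the scanned trajectory,
#'   columns successive line scans.
#' @param line_rate Line rate in Hz.
#' @param pixel_pitch Pixel pitch along the trajectory in micrometres.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(data, line_rate, pixel_pitch) {
  data <- as.matrix(data)
  if (ncol(data) < 2)
    stop_fibrescope("a kymograph needs at least 2 columns", "invalid_spec")
  if (!is_scalar_number(line_rate) || line_rate <= 0)
    stop_fibrescope("line_rate must be > 0", "invalid_spec")
  if (!is_scalar_number(pixel_pitch) || pixel_pitch <= 0)
    stop_fibrescope("pixel_pitch must be > 0", "invalid_spec")
  structure(list(data = data, line_rate = line_rate,
                 pixel_pitch = pixel_pitch),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d lines @ %g Hz, pitch %g um\n",
              nrow(x$data), ncol(x$data), x$line_rate, x$pixel_pitch))
  invisible(x)
}

#' Velocimetry estimator settings
#'
#' @param half_window Columns used on each side of the evaluated column
#'   (default 4, i.e. a 9-column window).
#' @param v_grid Candidate velocities in px/line; sorted, symmetric default
#'   `seq(-10, 10, by = 0.25)`.
#' @param min_valid_rows Minimum number of rows that must survive morphing
#'   for a candidate to be valid.
#' @return An object of class `velocimetry_config`.
#' @export
velocimetry_config <- function(half_window = 4,
                               v_grid = seq(-10, 10, by = 0.25),
                               min_valid_rows = 4) {
  if (half_window < 1)
    stop_fibrescope("half_window must be >= 1", "invalid_spec")
  if (length(v_grid) == 0)
    stop_fibrescope("v_grid must be non-empty", "invalid_spec")
  structure(list(half_window = as.integer(half_window),
                 v_grid = sort(v_grid),
                 min_valid_rows = as.integer(min_valid_rows)),
            class = "velocimetry_config")
}

#' Row-wise gain normalisation of a kymograph
#'
#' Maps every row affinely to mean 0 and standard deviation 1, removing the
#' row-to-row differences in fluorescence response along the trajectory.
#' Zero-variance rows are flagged (`attr(, "excluded_rows")`) and left at
#' zero, excluded from estimation.
#'
#' @param k A [kymograph()].
#' @return The normalised `kymograph` (idempotent), with attribute
#'   `normalized = TRUE`.
#' @export
normalize_rows <- function(k) {
  stopifnot(inherits(k, "kymograph"))
  m <- rowMeans(k$data)
  s <- apply(k$data, 1, stats::sd)
  flat <- s == 0 | !is.finite(s)
  if (all(flat))
    stop_fibrescope("all rows have zero variance", "degenerate_input")
  d <- (k$data - m) / ifelse(flat, 1, s)
  d[flat, ] <- 0
  out <- kymograph(d, k$line_rate, k$pixel_pitch)
  attr(out, "excluded_rows") <- which(flat)
  attr(out, "normalized") <- TRUE
  out
}

# Metric curve for one column over all candidate velocities: for candidate v
# the column at window offset delta is shifted vertically by round(v*delta)
# pixels; rows valid across the whole window are retained and the metric is
# the mean across retained rows of the standard deviation across the window's
# columns. Invalid candidates (too few valid rows) yield NA.
#' @noRd
metric_curve_column <- function(data, column, cfg, excluded_rows = integer(0)) {
  n_rows <- nrow(data); n_cols <- ncol(data)
  deltas <- seq(-cfg$half_window, cfg$half_window)
  deltas <- deltas[column + deltas >= 1 & column + deltas <= n_cols]
  wsize <- length(deltas)
  rows_ok <- rep(TRUE, n_rows)
  if (length(excluded_rows)) rows_ok[excluded_rows] <- FALSE
  vapply(cfg$v_grid, function(v) {
    shifts <- round(v * deltas)
    lo <- max(1 - min(shifts), 1)
    hi <- min(n_rows - max(shifts), n_rows)
    if (hi - lo + 1 < 2) return(NA_real_)
    rows <- lo:hi
    rows <- rows[rows_ok[rows]]
    if (length(rows) < cfg$min_valid_rows) return(NA_real_)
    w <- vapply(seq_along(deltas), function(i)
      data[rows + shifts[i], column + deltas[i]], numeric(length(rows)))
    mean(apply(w, 1, stats::sd))
  }, numeric(1))
}

# Pick the velocity from a metric curve: global minimum (ties broken toward
# smaller |v|), refined by a parabola through the minimum and its neighbours.
#' @noRd
pick_velocity <- function(metric, v_grid) {
  ok <- which(is.finite(metric))
  if (length(ok) == 0) return(NA_real_)
  mmin <- min(metric[ok])
  cand <- ok[metric[ok] <= mmin + 1e-15]
  i <- cand[which.min(abs(v_grid[cand]))]
  if (i > 1 && i < length(v_grid) &&
      is.finite(metric[i - 1]) && is.finite(metric[i + 1])) {
    step_lo <- v_grid[i] - v_grid[i - 1]
    step_hi <- v_grid[i + 1] - v_grid[i]
    off <- parabolic_offset(metric[i - 1], metric[i], metric[i + 1])
    v_grid[i] + off * (if (off >= 0) step_hi else step_lo)
  } else {
    v_grid[i]
  }
}

#' Velocity estimate at a single kymograph column
#'
#' @param k A [kymograph()] (normalised with [normalize_rows()]; applied
#'   automatically otherwise).
#' @param column Column (line scan) index.
#' @param cfg A [velocimetry_config()].
#' @return List with `v` (px/line), `metric` (one value per candidate,
#'   `NA` for invalid candidates) and `truncated` (TRUE when the window was
#'   clipped at a record edge).
#' @export
velocity_at <- function(k, column, cfg = velocimetry_config()) {
  stopifnot(inherits(k, "kymograph"))
  if (!isTRUE(attr(k, "normalized"))) k <- normalize_rows(k)
  if (column < 1 || column > ncol(k$data))
    stop_fibrescope("column outside the record", "index_error")
  metric <- metric_curve_column(k$data, column, cfg,
                                attr(k, "excluded_rows"))
  if (all(!is.finite(metric)))
    stop_fibrescope("no valid candidate velocity at this column",
                    "degenerate_input")
  truncated <- column - cfg$half_window < 1 ||
    column + cfg$half_window > ncol(k$data)
  list(v = pick_velocity(metric, cfg$v_grid), metric = metric,
       truncated = truncated)
}

# Vectorised metric over all columns for every candidate velocity, using
# NA-padded shifted copies of the record and running sum / sum-of-squares
# accumulators across the window.
#' @noRd
metric_matrix <- function(data, cfg, excluded_rows = integer(0)) {
  n_rows <- nrow(data); n_cols <- ncol(data)
  if (length(excluded_rows)) data[excluded_rows, ] <- NA_real_
  deltas <- seq(-cfg$half_window, cfg$half_window)
  n_v <- length(cfg$v_grid)
  metric <- matrix(NA_real_, n_v, n_cols)
  for (iv in seq_len(n_v)) {
    v <- cfg$v_grid[iv]
    cnt <- matrix(0, n_rows, n_cols)
    s1 <- matrix(0, n_rows, n_cols)
    s2 <- matrix(0, n_rows, n_cols)
    wsz <- matrix(0, 1, n_cols)
    for (d in deltas) {
      sh <- round(v * d)
      src_rows <- seq_len(n_rows) + sh
      src_cols <- seq_len(n_cols) + d
      ok_r <- src_rows >= 1 & src_rows <= n_rows
      ok_c <- src_cols >= 1 & src_cols <= n_cols
      m <- matrix(NA_real_, n_rows, n_cols)
      m[ok_r, ok_c] <- data[src_rows[ok_r], src_cols[ok_c]]
      have <- !is.na(m)
      cnt <- cnt + have
      m0 <- ifelse(have, m, 0)
      s1 <- s1 + m0
      s2 <- s2 + m0^2
      wsz[1, ] <- wsz[1, ] + ok_c
    }
    # rows are retained only where every in-record window column contributed
    full <- sweep(cnt, 2, wsz[1, ], `==`) & cnt >= 2
    sd2 <- (s2 - s1^2 / pmax(cnt, 1)) / pmax(cnt - 1, 1)
    sd2[!full] <- NA_real_
    sdv <- sqrt(pmax(sd2, 0))
    nvalid <- colSums(full)
    mcol <- colSums(sdv, na.rm = TRUE) / pmax(nvalid, 1)
    mcol[nvalid < cfg$min_valid_rows] <- NA_real_
    metric[iv, ] <- mcol
  }
  metric
}

#' Velocity trace over a whole kymograph
#'
#' Runs the morphing estimator at every column. Columns where no candidate
#' velocity is valid yield `NA` and are flagged as gaps.
#'
#' @inheritParams velocity_at
#' @return An object of class `velocity_trace`: data frame columns `t` (s)
#'   and `v` (px/line), with attributes `gaps` (flagged columns),
#'   `truncated` (edge columns), `units = "px_per_line"`, plus the source
#'   record's `line_rate` and `pixel_pitch`.
#' @export
velocity_trace <- function(k, cfg = velocimetry_config()) {
  stopifnot(inherits(k, "kymograph"))
  if (!isTRUE(attr(k, "normalized"))) k <- normalize_rows(k)
  n_cols <- ncol(k$data)
  metric <- metric_matrix(k$data, cfg, attr(k, "excluded_rows"))
  v <- vapply(seq_len(n_cols), function(cc)
    pick_velocity(metric[, cc], cfg$v_grid), numeric(1))
  trace <- data.frame(t = (seq_len(n_cols) - 1) / k$line_rate, v = v)
  structure(trace,
            gaps = which(is.na(v)),
            truncated = c(seq_len(min(cfg$half_window, n_cols)),
                          seq.int(max(n_cols - cfg$half_window + 1, 1), n_cols)),
            units = "px_per_line",
            line_rate = k$line_rate, pixel_pitch = k$pixel_pitch,
            class = c("velocity_trace", "data.frame"))
}

#' Convert a velocity trace to physical units
#'
#' `v[um/s] = v[px/line] * pixel_pitch[um] * line_rate[lines/s]`.
#'
#' @param trace A [velocity_trace()] in px/line.
#' @param k Optionally, the source [kymograph()] supplying `line_rate` and
#'   `pixel_pitch` if the trace lacks them.
#' @return The trace with `v` in um/s (`units = "um_per_s"`).
#' @export
to_physical <- function(trace, k = NULL) {
  lr <- if (!is.null(k)) k$line_rate else attr(trace, "line_rate")
  pp <- if (!is.null(k)) k$pixel_pitch else attr(trace, "pixel_pitch")
  if (is.null(lr) || is.null(pp))
    stop_fibrescope("line_rate / pixel_pitch metadata missing", "invalid_spec")
  if (identical(attr(trace, "units"), "um_per_s")) return(trace)
  out <- trace
  out$v <- trace$v * pp * lr
  attr(out, "units") <- "um_per_s"
  out
}

#' Power spectrum of a velocity trace
#'
#' Mean-removed periodogram with frequency resolution `1/duration`. Gaps in
#' the trace are linearly interpolated first and flagged.
#'
#' @param trace A [velocity_trace()] (uniform sampling).
#' @return Data frame with `frequency` (Hz) and `power`; interpolated gap
#'   columns in `attr(, "interpolated")`.
#' @export
power_spectrum <- function(trace) {
  v <- trace$v
  n <- length(v)
  if (n < 4)
    stop_fibrescope("trace too short for a spectrum (need >= 4 samples)",
                    "invalid_spec")
  gaps <- which(is.na(v))
  if (length(gaps) > 0) {
    ok <- which(!is.na(v))
    if (length(ok) < 2)
      stop_fibrescope("trace has too few valid samples", "degenerate_input")
    v[gaps] <- stats::approx(ok, v[ok], xout = gaps, rule = 2)$y
  }
  dt <- diff(trace$t[1:2])
  v <- v - mean(v)
  sp <- Mod(stats::fft(v))^2 / n
  nf <- floor(n / 2) + 1L
  out <- data.frame(frequency = (seq_len(nf) - 1) / (n * dt),
                    power = sp[seq_len(nf)])
  attr(out, "interpolated") <- gaps
  out
}
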