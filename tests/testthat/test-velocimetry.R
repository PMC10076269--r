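# Brute-force reimplementation of the morphing metric, straight from its
# definition, used as the oracle for the vectorised estimator.
oracle_metric <- function(data, column, half_window, v_grid,
                          min_valid_rows = 4) {
  n_rows <- nrow(data); n_cols <- ncol(data)
  deltas <- seq(-half_window, half_window)
  deltas <- deltas[column + deltas >= 1 & column + deltas <= n_cols]
  vapply(v_grid, function(v) {
    shifts <- round(v * deltas)
    rows <- which(vapply(seq_len(n_rows), function(r)
      all(r + shifts >= 1 & r + shifts <= n_rows), logical(1)))
    if (length(rows) < max(min_valid_rows, 2)) return(NA_real_)
    sds <- vapply(rows, function(r)
      stats::sd(vapply(seq_along(deltas), function(i)
        data[r + shifts[i], column + deltas[i]], numeric(1))), numeric(1))
    mean(sds)
  }, numeric(1))
}

test_that("row normalisation is affine, idempotent and gain-invariant", {
  set.seed(2)
  k <- kymograph(matrix(runif(64 * 20, 1, 3), 64, 20), 1000, 0.5)
  n1 <- normalize_rows(k)
  expect_equal(rowMeans(n1$data), rep(0, 64), tolerance = 1e-12)
  expect_equal(apply(n1$data, 1, sd), rep(1, 64), tolerance = 1e-12)
  n2 <- normalize_rows(n1)
  expect_equal(n2$data, n1$data, tolerance = 1e-12)
  gains <- runif(64, 0.5, 2)
  kg <- kymograph(k$data * gains, 1000, 0.5)
  expect_equal(normalize_rows(kg)$data, n1$data, tolerance = 1e-10)
})

test_that("zero-variance rows are excluded, an all-flat record rejected", {
  d <- matrix(runif(10 * 8), 10, 8)
  d[4, ] <- 7
  n <- normalize_rows(kymograph(d, 1000, 0.5))
  expect_equal(attr(n, "excluded_rows"), 4L)
  expect_true(all(n$data[4, ] == 0))
  expect_error(normalize_rows(kymograph(matrix(1, 5, 5), 1000, 0.5)),
               class = "degenerate_input")
})

test_that("the estimator metric matches the brute-force oracle", {
  set.seed(7)
  d <- matrix(rnorm(32 * 9), 32, 9)
  cfg <- velocimetry_config(half_window = 4, v_grid = seq(-3, 3, by = 0.5))
  k <- kymograph(d, 1000, 0.5)
  nk <- normalize_rows(k)
  for (col in c(1L, 3L, 5L, 9L)) {      # central and truncated windows
    got <- velocity_at(nk, col, cfg)$metric
    want <- oracle_metric(nk$data, col, 4, cfg$v_grid)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # the vectorised whole-record path agrees with the per-column path
  mm <- fibrescope:::metric_matrix(nk$data, cfg)
  for (col in seq_len(9))
    expect_equal(mm[, col],
                 fibrescope:::metric_curve_column(nk$data, col, cfg),
                 tolerance = 1e-12)
})

test_that("a uniform diagonal streak pattern reads slope 2", {
  rows <- seq_len(64)
  d <- vapply(seq_len(21), function(col)
    sin(2 * pi * (rows - 2 * col) / 16) +
      0.5 * cos(2 * pi * (rows - 2 * col) / 9), numeric(64))
  k <- kymograph(d, 1000, 0.5)
  est <- velocity_at(k, 11L)
  expect_lt(abs(est$v - 2), 0.05)
  expect_false(est$truncated)
  expect_true(velocity_at(k, 2L)$truncated)
})

test_that("flipping the record negates the velocity", {
  k <- make_rbc_kymograph(3, n_lines = 60, streak_density = 10, seed = 4)
  kf <- kymograph(k$data[nrow(k$data):1, ], k$line_rate, k$pixel_pitch)
  v <- velocity_at(k, 30L)$v
  vf <- velocity_at(kf, 30L)$v
  expect_lt(abs(v - 3), 0.3)
  expect_lt(abs(vf + v), 0.3)
})

test_that("a perfect tie is broken toward zero velocity", {
  # all rows share one time course: every candidate aligns perfectly
  g <- sin(seq_len(20))
  d <- matrix(rep(g, each = 16), 16, 20)
  k <- kymograph(d, 1000, 0.5)
  est <- velocity_at(k, 10L)
  expect_equal(est$v, 0)
  m <- est$metric[is.finite(est$metric)]
  expect_lt(diff(range(m)), 1e-12)   # every candidate aligns equally well
})

test_that("constant flow is recovered within 0.3 px/line at SNR 10", {
  k <- make_rbc_kymograph(3, n_lines = 400, streak_density = 10,
                          noise = "poisson", noise_level = 100, seed = 11)
  tr <- velocity_trace(k)
  keep <- setdiff(seq_len(400), c(attr(tr, "truncated"), attr(tr, "gaps")))
  v <- tr$v[keep]
  expect_lt(abs(mean(v) - 3) / 3, 0.05)
  expect_lt(sqrt(mean((v - 3)^2)), 0.3)
})

test_that("a slow sinusoidal modulation passes at full amplitude", {
  prof <- function(t) 3 + sin(2 * pi * 5 * t)
  k <- make_rbc_kymograph(prof, n_lines = 1000, streak_density = 10,
                          seed = 5)
  tr <- velocity_trace(k)
  keep <- setdiff(seq_len(1000), c(attr(tr, "truncated"), attr(tr, "gaps")))
  t_s <- tr$t[keep]; v <- tr$v[keep]
  fit <- stats::lm(v ~ sin(2 * pi * 5 * t_s) + cos(2 * pi * 5 * t_s))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.1)
  expect_lt(abs(stats::coef(fit)[1] - 3), 0.15)
  # keep the trace for the spectrum block below
  assign("sin5_trace", tr, envir = .fixtures)
})

test_that("a wider window averages sparse-streak scatter down", {
  k <- make_rbc_kymograph(3, n_lines = 400, streak_density = 3, seed = 6)
  rmse <- function(hw) {
    tr <- velocity_trace(k, velocimetry_config(half_window = hw))
    keep <- setdiff(seq_len(400),
                    c(attr(tr, "truncated"), attr(tr, "gaps")))
    sqrt(mean((tr$v[keep] - 3)^2))
  }
  expect_lt(rmse(8), rmse(4))
})

test_that("physical conversion multiplies by pitch and line rate", {
  tr <- structure(data.frame(t = c(0, 0.001), v = c(2, 0)),
                  units = "px_per_line", line_rate = 1000, pixel_pitch = 0.5,
                  class = c("velocity_trace", "data.frame"))
  ph <- to_physical(tr)
  expect_equal(ph$v, c(1000, 0))
  expect_identical(attr(ph, "units"), "um_per_s")
  expect_equal(to_physical(ph)$v, ph$v)   # idempotent
  bare <- structure(data.frame(t = 0, v = 1), units = "px_per_line")
  expect_error(to_physical(bare), class = "invalid_spec")
})

test_that("the power spectrum resolves the modulation frequency", {
  tr <- get("sin5_trace", envir = .fixtures)
  sp <- power_spectrum(tr)
  df <- sp$frequency[2]
  f_peak <- sp$frequency[-1][which.max(sp$power[-1])]  # skip DC
  expect_lt(abs(f_peak - 5), df + 1e-9)
  expect_error(power_spectrum(data.frame(t = c(0, 1), v = c(1, 2))),
               class = "invalid_spec")
})

test_that("two-tone and sub-0.1 Hz modulations appear as distinct peaks", {
  t_s <- (seq_len(4500) - 1) / 60          # 75 s at 60 Hz sampling
  v <- 3 + 0.5 * sin(2 * pi * 2 * t_s) + 0.3 * sin(2 * pi * 8 * t_s) +
    0.4 * sin(2 * pi * 0.08 * t_s)
  sp <- power_spectrum(data.frame(t = t_s, v = v))
  top <- sp$frequency[-1][order(sp$power[-1], decreasing = TRUE)[1:3]]
  df <- sp$frequency[2]
  expect_true(any(abs(top - 2) < df + 1e-9))
  expect_true(any(abs(top - 8) < df + 1e-9))
  expect_true(any(abs(top - 0.08) < df + 1e-9))
  expect_lt(min(top), 0.1)
})

test_that("gap columns are interpolated and reported by the spectrum", {
  t_s <- (seq_len(64) - 1) / 100
  v <- sin(2 * pi * 3 * t_s)
  v[c(10, 30)] <- NA
  sp <- power_spectrum(data.frame(t = t_s, v = v))
  expect_equal(attr(sp, "interpolated"), c(10L, 30L))
  expect_false(anyNA(sp$power))
})
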