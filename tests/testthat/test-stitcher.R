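# Smooth strictly positive random image: low-pass filtered white noise.
smooth_image <- function(n_rows, n_cols, seed = 1, cutoff = 0.15) {
  set.seed(seed)
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  fr <- function(n) c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  keep <- outer(abs(fr(n_rows)), abs(fr(n_cols)),
                function(a, b) sqrt(a^2 + b^2)) < cutoff
  s <- Re(stats::fft(stats::fft(z) * keep, inverse = TRUE)) / (n_rows * n_cols)
  s - min(s) + 0.1
}

test_that("floor subtraction matches the sorting oracle exactly", {
  x <- matrix(sample(1:100), 10, 10)
  out <- floor_subtract(x, fraction = 0.01)
  expect_equal(out, pmax(x - 1, 0))  # 1% of 100 px = the single minimum
  y <- matrix(rnorm(400), 20, 20)
  frac <- 0.05
  n_low <- ceiling(frac * length(y))
  oracle <- mean(sort(as.vector(y))[seq_len(n_low)])
  expect_equal(floor_subtract(y, frac), pmax(y - oracle, 0))
})

test_that("floor subtraction zeroes a constant frame and validates input", {
  expect_true(all(floor_subtract(matrix(7, 5, 5)) == 0))
  expect_error(floor_subtract(matrix(1, 2, 2), fraction = 0),
               class = "invalid_spec")
  expect_error(floor_subtract(matrix(1, 2, 2), fraction = 1),
               class = "invalid_spec")
})

test_that("floor subtraction maps over every frame of a record", {
  st <- list(list(matrix(1:4, 2, 2) + 10), list(matrix(1:4, 2, 2) + 20))
  rec <- scan_record(st, frame_rate = 1)
  out <- floor_subtract(rec, fraction = 0.25)
  expect_equal(out$stacks[[1]][[1]], pmax(matrix(1:4, 2, 2) + 10 - 11, 0))
  expect_equal(out$stacks[[2]][[1]], pmax(matrix(1:4, 2, 2) + 20 - 21, 0))
})

test_that("shift estimation recovers integer, zero and flat cases", {
  img <- smooth_image(60, 30, seed = 2)
  a <- img[1:50, ]
  b <- img[4:53, ]                               # b[r] = a[r + 3] exactly
  s <- estimate_shift(a, b)
  expect_lt(abs(as.numeric(s) - 3), 0.1)
  expect_s3_class(attr(s, "ncc"), "data.frame")
  expect_lt(abs(as.numeric(estimate_shift(a, a))), 0.1)
  expect_error(estimate_shift(matrix(1, 8, 8), matrix(1, 8, 8)),
               class = "degenerate_input")
  expect_error(estimate_shift(a, a[, 1:10]), class = "invalid_spec")
})

test_that("shift estimation resolves sub-pixel displacements", {
  # sample one smooth band-limited profile at integer rows and rows + 2.5
  r <- seq_len(64)
  f <- function(x) sin(2 * pi * x / 19) + 0.6 * cos(2 * pi * x / 7) +
    0.3 * sin(2 * pi * x / 31)
  a <- outer(f(r), c(1, 0.8, 1.2, 0.9))
  b <- outer(f(r + 2.5), c(1, 0.8, 1.2, 0.9))
  s <- as.numeric(estimate_shift(a, b))
  expect_lt(abs(s - 2.5), 0.25)
})

test_that("speed estimation averages pairwise shifts of a uniform drift", {
  img <- smooth_image(120, 24, seed = 3)
  stacks <- lapply(0:4, function(k) list(img[(1 + 3 * k):(40 + 3 * k), ]))
  rec <- scan_record(stacks, frame_rate = 1)
  sp <- estimate_speed(rec)
  expect_lt(abs(as.numeric(sp) - 3), 0.1)
  expect_length(attr(sp, "pair_shifts"), 4L)
  # intensity scaling leaves the correlation-based estimate unchanged
  rec10 <- scan_record(lapply(stacks, function(s) list(10 * s[[1]])), 1)
  expect_equal(as.numeric(estimate_speed(rec10)), as.numeric(sp),
               tolerance = 1e-10)
  expect_error(estimate_speed(scan_record(stacks[1:2], 1)),
               class = "invalid_spec")
})

test_that("stitching averages the overlap and counts coverage", {
  f1 <- matrix(2, 6, 3); f2 <- matrix(4, 6, 3)
  rec <- scan_record(list(list(f1), list(f2)), frame_rate = 1)
  sv <- stitch(rec, speed = 2)
  expect_equal(dim(sv$volume), c(1L, 8L, 3L))
  expect_true(all(sv$volume[1, 1:2, ] == 2))   # only stack 1
  expect_true(all(sv$volume[1, 3:6, ] == 3))   # overlap mean of 2 and 4
  expect_true(all(sv$volume[1, 7:8, ] == 4))   # only stack 2
  expect_equal(sv$count[1, , 1], c(1L, 1L, 2L, 2L, 2L, 2L, 1L, 1L))
  expect_error(stitch(rec, speed = 0), class = "invalid_spec")
})

test_that("identical frames stitch to a constant volume", {
  f <- matrix(5, 6, 3)
  rec <- scan_record(rep(list(list(f)), 4), frame_rate = 1)
  sv <- stitch(rec, speed = 2)
  expect_true(all(sv$volume[sv$count > 0] == 5))
})

test_that("a drifting phantom is reassembled at the right speed", {
  dens <- smooth_image(40, 160, seed = 8)     # scene: x = 40, drift axis = 160
  sc <- scene(array(dens, c(40, 160, 1)), voxel_size = 0.5)
  plan <- scan_plan("raster", field_of_view = c(20, 10), pixel_pitch = 0.5)
  # 1 um/s at 0.25 Hz and 0.5 um voxels -> exactly 8 px per stack
  rec <- make_drift_record(sc, speed = 1, plan, frame_rate = 0.25,
                           n_stacks = 8)
  truth <- attr(rec, "ground_truth")
  expect_equal(truth$speed_px_per_frame, 8)
  sp <- as.numeric(estimate_speed(rec))
  expect_lt(abs(sp - 8) / 8, 0.05)
  sv <- stitch(rec, sp)
  ref <- t(dens[, seq_len(dim(sv$volume)[2])])  # global rows x columns
  expect_gt(ncc(sv$volume[1, , ], ref), 0.95)
  rmse <- sqrt(mean((sv$volume[1, , ] - ref)^2)) / diff(range(ref))
  expect_lt(rmse, 0.02)
})
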