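# Single fluorescent bead on the fibre axis at the facet plane.
bead_scene <- function(z = 0, amp = 1) {
  d <- array(0, c(21, 21, 1))
  d[11, 11, 1] <- amp
  scene(d, voxel_size = 0.3, origin_z = z)
}

test_that("scan plan geometry follows fov / pitch", {
  plan <- scan_plan("raster", field_of_view = c(100, 5.7),
                    pixel_pitch = 1, plane_offsets = seq(-10, 10, by = 2.5))
  expect_equal(plan$n_x, 100L)
  expect_equal(plan$n_y, 6L)
  expect_length(plan$plane_offsets, 9L)
  expect_error(scan_plan("line", trajectory = NULL), class = "invalid_spec")
  expect_error(scan_plan("raster", plane_offsets = c(0, NA)),
               class = "invalid_spec")
})

test_that("an empty scene produces an all-zero frame", {
  fx <- small_setup()
  sc <- scene(array(0, c(5, 5, 1)), voxel_size = 0.5)
  plan <- scan_plan("raster", field_of_view = c(3, 3), pixel_pitch = 0.6)
  fr <- scan_frame(fx$tm, fx$fwd, sc, plan)
  expect_equal(dim(fr), c(5L, 5L))
  expect_true(all(fr == 0))
})

test_that("the noiseless signal is linear in the scene density", {
  fx <- small_setup()
  plan <- scan_plan("raster", field_of_view = c(3, 3), pixel_pitch = 0.6)
  a <- bead_scene()
  b <- bead_scene(amp = 2)
  d_off <- array(0, c(21, 21, 1)); d_off[8, 14, 1] <- 1.5
  c_sc <- scene(d_off, voxel_size = 0.3)
  sum_sc <- scene(a$density + c_sc$density, voxel_size = 0.3)
  fr <- function(s) unclass(scan_frame(fx$tm, fx$fwd, s, plan))
  expect_equal(fr(b), 2 * fr(a), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fr(sum_sc), fr(a) + fr(c_sc), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("imaging a point bead reproduces the excitation PSF width", {
  fx <- small_setup()
  plan <- scan_plan("raster", field_of_view = c(6, 6), pixel_pitch = 0.3)
  fr <- scan_frame(fx$tm, fx$fwd, bead_scene(), plan)
  pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  xs <- (seq_len(plan$n_x) - (plan$n_x + 1) / 2) * plan$pixel_pitch
  fwhm_img <- profile_fwhm(xs, fr[pk[1], ])
  # reference: intensity profile of the synthesised focus itself
  foc <- synthesize_focus(fx$tm, fx$fwd, c(33L, 33L))
  inten <- Mod(foc$field)^2
  fpk <- which(inten == max(inten), arr.ind = TRUE)[1, ]
  fwhm_psf <- profile_fwhm(fx$grid$axis, inten[, fpk[2]])
  expect_lt(abs(fwhm_img - fwhm_psf) / fwhm_psf, 0.15)
})

test_that("the z-stack is brightest at the bead's plane", {
  fx <- small_setup()
  plan <- scan_plan("raster", field_of_view = c(3, 3), pixel_pitch = 0.6,
                    plane_offsets = c(0, 2.5, 5))
  ladder <- refocus_ladder(fx$tm, plan$plane_offsets)
  st <- scan_zstack(ladder, fx$fwd, bead_scene(z = 2.5), plan)
  totals <- vapply(st, max, numeric(1))
  expect_equal(which.max(totals), 2L)
  expect_equal(attr(st[[2]], "plane_offset"), 2.5)
})

test_that("plane lookup is by offset, independent of ladder order", {
  fx <- small_setup()
  plan <- scan_plan("raster", field_of_view = c(3, 3), pixel_pitch = 0.6,
                    plane_offsets = c(0, 2.5))
  ladder <- refocus_ladder(fx$tm, c(2.5, 0))   # reversed order
  fr <- scan_frame(ladder, fx$fwd, bead_scene(), plan, plane = 1L)
  fr_direct <- scan_frame(fx$tm, fx$fwd, bead_scene(), plan, plane = 1L)
  expect_equal(unclass(fr), unclass(fr_direct), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(scan_frame(ladder, fx$fwd, bead_scene(), plan, plane = 3L),
               regexp = "no transmission matrix for plane offset",
               class = "missing_plane")
})

test_that("static line scans repeat the same column", {
  fx <- small_setup()
  traj <- cbind(x = 0, y = seq(-2.25, 2.25, by = 0.3))
  plan <- scan_plan("line", plane_offsets = 0, rate = 10, trajectory = traj)
  ky <- scan_line(fx$tm, fx$fwd, bead_scene(), plan, n_sweeps = 5)
  expect_s3_class(ky, "kymograph")
  expect_equal(dim(ky$data), c(nrow(traj), 5L))
  expect_true(all(ky$data == ky$data[, 1]))
  expect_equal(ky$pixel_pitch, 0.3, tolerance = 1e-12)
  expect_equal(ky$line_rate, 10)
})

test_that("a drifting bead advances one trajectory point per sweep", {
  fx <- small_setup()
  # trajectory points on exact grid-sample positions (the 64-px grid has
  # pixel centres at 0.15 + 0.3 k), bead starting on the row-9 position
  traj <- cbind(x = -0.15, y = seq(-2.25, 2.25, by = 0.3))
  plan <- scan_plan("line", plane_offsets = 0, rate = 10, trajectory = traj)
  d <- array(0, c(21, 21, 1)); d[11, 11, 1] <- 1
  sc <- scene(d, voxel_size = 0.3, origin = c(-3 - 0.15, -3 + 0.15, 0))
  # vy = 3 um/s at 10 Hz and 0.3 um spacing -> exactly 1 row per sweep
  ky <- scan_line(fx$tm, fx$fwd, sc, plan, n_sweeps = 6, drift = c(0, 3))
  peaks <- apply(ky$data, 2, which.max)
  expect_equal(peaks[1], 9L, ignore_attr = TRUE)
  expect_equal(diff(peaks), rep(1L, 5L), ignore_attr = TRUE)
})

test_that("shot noise is seeded and reproducible", {
  fx <- small_setup()
  plan <- scan_plan("raster", field_of_view = c(3, 3), pixel_pitch = 0.6)
  f1 <- scan_frame(fx$tm, fx$fwd, bead_scene(), plan, noise_seed = 3)
  f2 <- scan_frame(fx$tm, fx$fwd, bead_scene(), plan, noise_seed = 3)
  f3 <- scan_frame(fx$tm, fx$fwd, bead_scene(), plan, noise_seed = 4)
  expect_identical(unclass(f1), unclass(f2))
  expect_false(identical(unclass(f1), unclass(f3)))
})

test_that("roi traces subtract the background and keep sweep timing", {
  mk <- function(vals) kymograph(matrix(vals, 4, 3, byrow = TRUE),
                                 line_rate = 10, pixel_pitch = 0.5)
  roi <- mk(c(2, 4, 6))
  bg <- mk(c(1, 1, 1))
  tr <- roi_traces(list(roi, bg), background_index = 2)
  expect_equal(tr$t, c(0, 0.1, 0.2))
  expect_equal(tr$roi1, c(1, 3, 5))
  expect_error(roi_traces(list(roi), 1), class = "invalid_spec")
  short <- kymograph(matrix(1, 4, 2), line_rate = 10, pixel_pitch = 0.5)
  expect_error(roi_traces(list(roi, short), 2), class = "invalid_spec")
})
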