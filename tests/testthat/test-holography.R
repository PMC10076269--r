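test_that("input basis elements are unit power with distinct tilts", {
  fx <- small_setup()
  b <- fx$basis
  pw <- colSums(Mod(b$fields)^2) * fx$grid$pitch^2
  expect_equal(pw, rep(1, b$n_elements), tolerance = 1e-10)
  expect_false(any(duplicated(t(b$tilts))))
  kmax <- sqrt(colSums(b$tilts^2))
  expect_true(all(kmax <= 2 * pi * fx$spec$na / fx$spec$wavelength + 1e-12))
})

test_that("a single-element basis is the flat zero-tilt field", {
  fx <- small_setup()
  b1 <- make_input_basis(1L, fx$grid, fx$spec)
  expect_equal(as.vector(b1$tilts), c(0, 0))
  f <- matrix(b1$fields[, 1], fx$grid$n_pixels)
  inside <- Mod(f) > 0
  expect_gt(sum(inside), 0)
  expect_lt(diff(range(Mod(f)[inside])), 1e-12)  # constant amplitude
  expect_lt(diff(range(Arg(f)[inside])), 1e-12)  # constant phase
})

test_that("an oversized basis errors naming the maximum", {
  fx <- small_setup()
  expect_error(make_input_basis(1e6, fx$grid, fx$spec),
               regexp = "exceeds the [0-9]+ distinguishable tilts",
               class = "invalid_spec")
})

test_that("phase-conjugation focus peaks at the requested target", {
  fx <- small_setup()
  target <- c(25L, 40L)
  foc <- synthesize_focus(fx$tm, fx$fwd, target)
  intensity <- Mod(foc$field)^2
  idx <- (target[2] - 1L) * fx$grid$n_pixels + target[1]
  expect_equal(which.max(intensity), idx)
})

test_that("kinoform coefficients reproduce the rendered modulation", {
  fx <- small_setup()
  mod <- phase_conjugate_kinoform(fx$tm, c(33L, 33L))
  rendered <- matrix(fx$basis$fields %*% mod$coef, fx$grid$n_pixels)
  expect_equal(rendered, mod$field, tolerance = 1e-10)
  pw <- sum(Mod(mod$field)^2) * fx$grid$pitch^2
  expect_equal(pw, 1, tolerance = 1e-10)
  expect_error(phase_conjugate_kinoform(fx$tm, 1e9), class = "index_error")
})

test_that("enhancement grows with the number of basis elements", {
  fx <- small_setup()
  enh <- vapply(c(15L, 30L, 60L), function(nb) {
    basis <- make_input_basis(nb, fx$grid, fx$spec)
    fwd <- ground_truth_operator(fx$modes, basis, 1, seed = 2)
    tm <- acquire_tm(fwd, basis)
    synthesize_focus(tm, fwd, c(33L, 33L))$report$enhancement
  }, numeric(1))
  expect_true(all(diff(enh) > 0))
  fit <- stats::lm(enh ~ n, data = data.frame(n = c(15, 30, 60), enh = enh))
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("Lee binarisation of a flat field is a regular carrier grating", {
  grid <- field_grid(64L, 0.3)
  flat <- modulation(matrix(1 + 0i, 64, 64), "complex", grid = grid)
  car <- carrier_spec(freq = c(0.25, 0))
  pat <- binarize_lee(flat, car)
  expect_true(all(pat$field %in% c(0, 1)))
  expect_equal(pat$field[1:60, ], pat$field[5:64, ])  # period 4 px in rows
  expect_true(all(pat$field[1, ] == pat$field[1, 1]))  # constant along cols
})

test_that("binary encoding round-trips through first-order decoding", {
  # smooth vortex-free complex field: low-pass amplitude in [0.3, 1] and a
  # low-pass phase of ~2 rad rms, on a 256^2 grid
  n <- 256L
  lowpass <- function(seed, cutoff = 0.015) {
    set.seed(seed)
    z <- matrix(rnorm(n^2), n)
    f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
    keep <- outer(abs(f), abs(f), function(a, b) sqrt(a^2 + b^2)) < cutoff
    Re(stats::fft(stats::fft(z) * keep, inverse = TRUE)) / n^2
  }
  a <- lowpass(1); a <- 0.3 + 0.7 * (a - min(a)) / diff(range(a))
  ph <- lowpass(2); ph <- ph / stats::sd(ph) * 2
  sm <- a * exp(1i * ph)
  m <- modulation(sm, "complex")
  car <- carrier_spec()
  pat <- binarize_lee(m, car)
  expect_true(all(pat$field %in% c(0, 1)))
  dec <- decode_first_order(pat, car)
  rho <- Mod(sum(Conj(dec$field) * sm)) /
    sqrt(sum(Mod(dec$field)^2) * sum(Mod(sm)^2))
  expect_gt(rho, 0.99)
  # determinism
  expect_identical(pat$field, binarize_lee(m, car)$field)
})

test_that("decoding a pure carrier grating gives a uniform field", {
  flat <- modulation(matrix(1 + 0i, 64, 64), "complex")
  car <- carrier_spec(freq = c(0.25, 0))
  dec <- decode_first_order(binarize_lee(flat, car), car)
  a <- Mod(dec$field)
  expect_lt(stats::sd(a) / mean(a), 1e-6)
})

test_that("binarised kinoform retains most of the focus enhancement", {
  fx <- small_setup()
  target <- c(33L, 33L)
  ideal <- synthesize_focus(fx$tm, fx$fwd, target)
  # render the kinoform on a 4x finer (DMD-like) pixel grid before
  # binarising, as the physical modulator resolves the speckle grains with
  # many mirrors each; exact for the NA-band-limited kinoform
  up <- 4L
  fine <- fibrescope:::fft_upsample(ideal$modulation$field, up)
  car <- carrier_spec()
  dec <- decode_first_order(binarize_lee(modulation(fine, "complex"), car),
                            car)
  n <- fx$grid$n_pixels
  coarse <- dec$field[up * (seq_len(n) - 1) + 1, up * (seq_len(n) - 1) + 1]
  f <- coarse / sqrt(sum(Mod(coarse)^2) * fx$grid$pitch^2)
  out <- apply_forward(fx$fwd, matrix(f, n))
  rep_bin <- focus_metrics(out, fx$grid)
  expect_gte(rep_bin$enhancement, 0.7 * ideal$report$enhancement)
})

test_that("carrier and modulation containers validate their invariants", {
  expect_error(carrier_spec(freq = c(0, 0)), class = "invalid_spec")
  expect_error(carrier_spec(freq = c(0.6, 0.3)), class = "invalid_spec")
  expect_error(modulation(matrix(0.5, 2, 2), "binary"), class = "invalid_spec")
  flat <- modulation(matrix(1, 2, 2), "binary")
  expect_error(binarize_lee(flat), class = "invalid_spec")
})
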