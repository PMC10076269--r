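# Shared fixtures, memoised across test files (helpers are sourced once per
# test run, so the cache environment persists).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small fast fibre used by most unit tests: 10 um core on a 64^2 grid.
small_setup <- function() fixture("small", function() {
  spec <- fiber_spec(10, 0.37, 0.488)
  grid <- field_grid(64L, 0.3)
  modes <- solve_modes(spec, grid)
  basis <- make_input_basis(60L, grid, spec)
  fwd <- ground_truth_operator(modes, basis, coupling_strength = 1, seed = 2)
  tm <- acquire_tm(fwd, basis)
  list(spec = spec, grid = grid, modes = modes, basis = basis,
       fwd = fwd, tm = tm)
})

# Full-width-at-half-maximum of a sampled 1-D profile, linear interpolation.
profile_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  cross <- function(idx_seq) {
    for (j in idx_seq) {
      k <- j + sign(i - j)
      if ((y[j] - half) * (y[k] - half) <= 0 && y[j] != y[k]) {
        f <- (half - y[j]) / (y[k] - y[j])
        return(x[j] + f * (x[k] - x[j]))
      }
    }
    NA_real_
  }
  lo <- cross(seq(1, i - 1))
  hi <- cross(seq(length(y), i + 1))
  hi - lo
}

# Normalised cross-correlation between two equal-shaped arrays.
ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  stats::cor(a, b)
}
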