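# Guided-mode model of a step-index multimode fibre under the weakly guiding
# (scalar LP) approximation, and a seeded ground-truth light-transport
# operator standing in for the physical fibre during simulated calibration.

#' Step-index multimode fibre specification
#'
#' Defines the optical fibre by its core diameter, numerical aperture and the
#' vacuum wavelength of the laser. The core index is derived from the cladding
#' index and the NA as `n_core = sqrt(n_clad^2 + na^2)`.
#'
#' @param core_diameter Core diameter in micrometres.
#' @param na Numerical aperture (dimensionless).
#' @param wavelength Vacuum wavelength in micrometres.
#' @param n_clad Cladding refractive index; defaults to 1.45 (fused silica).
#' @param length Fibre length in millimetres (metadata; sets the accumulated
#'   per-mode propagation phase of the ground-truth operator).
#' @return An object of class `fiber_spec`.
#' @examples
#' fiber_spec(core_diameter = 20, na = 0.37, wavelength = 0.488)
#' @export
fiber_spec <- function(core_diameter, na, wavelength, n_clad = 1.45,
                       length = 27) {
  stopifnot(is_scalar_number(core_diameter), is_scalar_number(na),
            is_scalar_number(wavelength), is_scalar_number(n_clad))
  if (core_diameter <= 0) stop_fibrescope("core_diameter must be > 0", "invalid_spec")
  if (wavelength <= 0) stop_fibrescope("wavelength must be > 0", "invalid_spec")
  n_core <- sqrt(n_clad^2 + na^2)
  if (na <= 0 || na >= n_core)
    stop_fibrescope("na must satisfy 0 < na < n_core", "invalid_spec")
  structure(list(core_diameter = core_diameter, na = na,
                 wavelength = wavelength, n_clad = n_clad,
                 n_core = n_core, length = length),
            class = "fiber_spec")
}

#' Normalised frequency (V number) of a fibre
#'
#' @param spec A [fiber_spec()].
#' @return `pi * core_diameter * na / wavelength`.
#' @export
v_number <- function(spec) {
  pi * spec$core_diameter * spec$na / spec$wavelength
}

#' Square sampling grid for transverse fields
#'
#' The fibre axis is at the grid centre; pixel centres are at
#' `(i - (n+1)/2) * pitch`. Validity with respect to a fibre (Nyquist pitch,
#' core coverage) is checked by [solve_modes()].
#'
#' @param n_pixels Pixels per side.
#' @param pitch Pixel pitch in micrometres.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(n_pixels, pitch) {
  stopifnot(is_scalar_number(n_pixels), is_scalar_number(pitch),
            n_pixels >= 2, pitch > 0)
  n_pixels <- as.integer(n_pixels)
  ax <- (seq_len(n_pixels) - (n_pixels + 1) / 2) * pitch
  structure(list(n_pixels = n_pixels, pitch = pitch, axis = ax),
            class = "field_grid")
}

# Pixel-centre coordinates (x varies along rows, y along columns) and polar
# coordinates about the fibre axis, as n x n matrices.
#' @noRd
grid_coords <- function(grid) {
  x <- matrix(grid$axis, grid$n_pixels, grid$n_pixels)
  y <- t(x)
  list(x = x, y = y, r = sqrt(x^2 + y^2), phi = atan2(y, x))
}

# Ratio K_{l+1}(w)/K_l(w) via exponentially scaled Bessel K, with the uniform
# large-order asymptotic as fallback where the scaled values overflow.
#' @noRd
bessel_k_ratio <- function(w, l) {
  kl  <- suppressWarnings(besselK(w, l,     expon.scaled = TRUE))
  kl1 <- suppressWarnings(besselK(w, l + 1, expon.scaled = TRUE))
  r <- kl1 / kl
  bad <- !is.finite(r)
  if (any(bad)) r[bad] <- (l + sqrt(l^2 + w[bad]^2)) / w[bad]
  r
}

# LP characteristic function whose roots in u of (0, V) are the guided
# LP(l, m) modes: f(u) = u J_{l+1}(u) - w K_{l+1}(w)/K_l(w) J_l(u),
# with u^2 + w^2 = V^2. Free of poles because K_l(w) > 0 for w > 0.
#' @noRd
lp_dispersion <- function(u, l, V) {
  w <- sqrt(pmax(V^2 - u^2, 1e-300))
  u * suppressWarnings(besselJ(u, l + 1)) -
    w * bessel_k_ratio(w, l) * suppressWarnings(besselJ(u, l))
}

# Bracketing intervals for all roots of lp_dispersion for one azimuthal order,
# by sign-change scanning on a uniform u grid. Underflowed (exact zero) values
# are skipped so that high-order J underflow does not fabricate roots.
#' @noRd
lp_root_brackets <- function(l, V, du = 0.02) {
  u <- seq(du, V * (1 - 1e-9), by = du)
  if (length(u) < 2) return(matrix(numeric(0), 0, 2))
  f <- lp_dispersion(u, l, V)
  keep <- is.finite(f) & f != 0
  u <- u[keep]; f <- f[keep]
  if (length(u) < 2) return(matrix(numeric(0), 0, 2))
  idx <- which(diff(sign(f)) != 0)
  cbind(u[idx], u[idx + 1])
}

#' Count the guided modes of a step-index fibre
#'
#' Counts the roots of the LP characteristic equation over all azimuthal
#' orders, then multiplies `l > 0` families by two for the two azimuthal
#' orientations and every spatial mode by two for polarisation. For large V
#' the total approaches `V^2/2`.
#'
#' @param spec A [fiber_spec()].
#' @param du Scan step in normalised transverse phase `u` used for root
#'   bracketing.
#' @return Total number of guided modes (orientations and polarisations
#'   included).
#' @examples
#' count_modes(fiber_spec(100, 0.37, 0.488))  # about 28,000
#' @export
count_modes <- function(spec, du = 0.02) {
  V <- v_number(spec)
  total <- 0
  l <- 0L
  repeat {
    nr <- nrow(lp_root_brackets(l, V, du))
    if (nr == 0L) break
    total <- total + nr * (if (l == 0L) 1 else 2)
    l <- l + 1L
  }
  as.integer(round(total * 2))  # two polarisation states per spatial mode
}

#' Solve the guided LP modes of a step-index fibre on a grid
#'
#' Finds all guided LP(l, m) modes (Bessel-J core / Bessel-K cladding radial
#' profiles matched at the core boundary), renders their transverse profiles
#' on the supplied grid and power-normalises them. Modes are returned sorted
#' by descending propagation constant; `l > 0` families appear with both
#' cosine and sine azimuthal orientations.
#'
#' @param spec A [fiber_spec()].
#' @param grid A [field_grid()]; its pitch must satisfy the Nyquist bound
#'   `pitch <= wavelength / (4 * na)` and it must cover the core.
#' @param du Root-bracketing scan step in `u`.
#' @return An object of class `mode_set` with elements `spec`, `grid`,
#'   `table` (data frame with columns `l`, `m`, `u`, `w`, `beta`,
#'   `orientation`) and `profiles` (matrix, one power-normalised flattened
#'   profile per column, ordered as `table`).
#' @export
solve_modes <- function(spec, grid, du = 0.02) {
  stopifnot(inherits(spec, "fiber_spec"), inherits(grid, "field_grid"))
  nyq <- spec$wavelength / (4 * spec$na)
  if (grid$pitch > nyq)
    stop_fibrescope(sprintf(
      "grid pitch %.4g exceeds the Nyquist pitch %.4g um for NA %.3g",
      grid$pitch, nyq, spec$na), "sampling_error")
  if (grid$n_pixels * grid$pitch < spec$core_diameter)
    stop_fibrescope("grid does not cover the fibre core", "sampling_error")

  V <- v_number(spec)
  k <- 2 * pi / spec$wavelength
  a <- spec$core_diameter / 2

  roots <- list(); l <- 0L
  repeat {
    br <- lp_root_brackets(l, V, du)
    if (nrow(br) == 0L) break
    u_l <- vapply(seq_len(nrow(br)), function(i) {
      stats::uniroot(lp_dispersion, lower = br[i, 1], upper = br[i, 2],
                     l = l, V = V, tol = 1e-12)$root
    }, numeric(1))
    roots[[l + 1L]] <- data.frame(l = l, m = seq_along(u_l), u = u_l)
    l <- l + 1L
  }
  if (length(roots) == 0L)
    stop_fibrescope("no guided mode for this fibre/wavelength", "degenerate_input")
  tab <- do.call(rbind, roots)
  tab$w <- sqrt(pmax(V^2 - tab$u^2, 0))
  tab$beta <- sqrt((k * spec$n_core)^2 - (tab$u / a)^2)

  # duplicate l > 0 rows for the two orientations, then sort by descending beta
  ori <- rep("cos", nrow(tab))
  tab$orientation <- ori
  sin_rows <- tab[tab$l > 0L, ]
  if (nrow(sin_rows) > 0) {
    sin_rows$orientation <- "sin"
    tab <- rbind(tab, sin_rows)
  }
  tab <- tab[order(-tab$beta, tab$l, tab$orientation), ]
  rownames(tab) <- NULL

  co <- grid_coords(grid)
  r <- as.vector(co$r); phi <- as.vector(co$phi)
  inside <- r <= a
  profiles <- matrix(0, grid$n_pixels^2, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    li <- tab$l[i]; ui <- tab$u[i]; wi <- tab$w[i]
    rad <- numeric(length(r))
    jl_a <- besselJ(ui, li)
    rad[inside] <- suppressWarnings(besselJ(ui * r[inside] / a, li)) / jl_a
    rad[!inside] <- bessel_k_profile(wi * r[!inside] / a, wi, li)
    ang <- if (tab$orientation[i] == "sin") sin(li * phi) else cos(li * phi)
    p <- rad * ang
    nrm <- sqrt(sum(p^2) * grid$pitch^2)
    if (nrm == 0)
      stop_fibrescope("mode unresolvable on this grid", "degenerate_input")
    profiles[, i] <- p / nrm
  }
  structure(list(spec = spec, grid = grid, table = tab, profiles = profiles),
            class = "mode_set")
}

# Cladding radial profile K_l(x)/K_l(w) evaluated through exponentially scaled
# Bessel K; where even the scaled values overflow (very high orders) the
# continuity-preserving exponential-decay surrogate is used.
#' @noRd
bessel_k_profile <- function(x, w, l) {
  num <- suppressWarnings(besselK(x, l, expon.scaled = TRUE))
  den <- suppressWarnings(besselK(w, l, expon.scaled = TRUE))
  out <- (num / den) * exp(w - x)
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- exp(w - x[bad]) * sqrt(w / x[bad])
  out
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf(
    "<mode_set> %d spatial modes (V = %.2f), core %g um, NA %g, lambda %g um\n",
    ncol(x$profiles), v_number(x$spec), x$spec$core_diameter, x$spec$na,
    x$spec$wavelength))
  invisible(x)
}

# Loewdin (symmetric) orthonormalisation of the sampled mode profiles in the
# grid inner product, so that projection onto the mode subspace is an exact
# orthogonal projection.
#' @noRd
orthonormal_profiles <- function(modes) {
  g <- crossprod(modes$profiles) * modes$grid$pitch^2
  e <- eigen(g, symmetric = TRUE)
  if (min(e$values) < 1e-10)
    stop_fibrescope("mode profiles numerically degenerate on this grid",
                    "sampling_error")
  w <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  modes$profiles %*% w
}

#' Seeded ground-truth transport operator of a calibrated fibre segment
#'
#' Stands in for the physical fibre plus relay optics: input fields are
#' projected onto the guided-mode basis, propagated with per-mode phases
#' `exp(i beta L)`, mixed by a seeded unitary that blends the identity
#' (`coupling_strength = 0`) with a Haar-random unitary
#' (`coupling_strength = 1`), and rendered back on the output grid. The
#' mode-space matrix is exactly unitary for every coupling strength, and the
#' operator is deterministic for a fixed seed.
#'
#' @param modes A [solve_modes()] result.
#' @param input_basis An [make_input_basis()] result on the same grid.
#' @param coupling_strength Fraction in `[0, 1]` of random inter-modal mixing.
#' @param seed Integer seed for the random unitary.
#' @return An object of class `forward_operator` with the full complex map
#'   `matrix` (output grid samples x input basis elements), the unitary
#'   `mode_matrix`, and the orthonormalised rendering basis.
#' @export
ground_truth_operator <- function(modes, input_basis, coupling_strength = 1,
                                  seed = 1) {
  stopifnot(inherits(modes, "mode_set"))
  if (ncol(modes$profiles) == 0L)
    stop_fibrescope("empty mode set", "degenerate_input")
  if (!is_scalar_number(coupling_strength) ||
      coupling_strength < 0 || coupling_strength > 1)
    stop_fibrescope("coupling_strength must lie in [0, 1]", "invalid_spec")
  if (inherits(input_basis, "input_basis")) {
    if (!identical(input_basis$grid$n_pixels, modes$grid$n_pixels) ||
        !identical(input_basis$grid$pitch, modes$grid$pitch))
      stop_fibrescope("input basis and modes use different grids", "invalid_spec")
    basis_fields <- input_basis$fields
  } else {
    basis_fields <- input_basis  # plain matrix of flattened fields
  }

  n_modes <- ncol(modes$profiles)
  psi <- orthonormal_profiles(modes)
  length_um <- modes$spec$length * 1e3
  d_phase <- exp(1i * (modes$table$beta %% (2 * pi / length_um)) * length_um)
  u_mix <- with_seed(seed, random_unitary(n_modes))
  u_c <- unitary_power(u_mix, coupling_strength)
  mode_matrix <- sweep(u_c, 2, d_phase, `*`)  # U %*% diag(exp(i beta L))

  op <- structure(list(
    modes_ortho = psi,
    mode_matrix = mode_matrix,
    grid = modes$grid,
    spec = modes$spec,
    seed = as.integer(seed),
    coupling_strength = coupling_strength
  ), class = "forward_operator")
  op$matrix <- apply_forward(op, basis_fields)
  op
}

#' Push fields through a forward operator
#'
#' @param forward A [ground_truth_operator()] result.
#' @param fields A complex matrix with one flattened input field per column
#'   (or a single field as an `n x n` matrix).
#' @return Matrix of flattened output fields, one column per input.
#' @export
apply_forward <- function(forward, fields) {
  stopifnot(inherits(forward, "forward_operator"))
  single <- is.matrix(fields) && nrow(fields) == forward$grid$n_pixels &&
    ncol(fields) == forward$grid$n_pixels
  f <- if (single) matrix(as.vector(fields), ncol = 1) else fields
  coef <- (Conj(t(forward$modes_ortho)) %*% f) * forward$grid$pitch^2
  out <- forward$modes_ortho %*% (forward$mode_matrix %*% coef)
  if (single) matrix(out, forward$grid$n_pixels) else out
}

#' Project a field onto the guided-mode subspace
#'
#' Returns the mode coefficients of a field in the operator's orthonormalised
#' mode basis. The coefficient power `sum(|c|^2)` never exceeds the field
#' power (Bessel inequality).
#'
#' @inheritParams apply_forward
#' @param field A complex field (`n x n` matrix or flattened vector).
#' @return Complex coefficient vector.
#' @export
project_modes <- function(forward, field) {
  as.vector((Conj(t(forward$modes_ortho)) %*% as.vector(field)) *
              forward$grid$pitch^2)
}

#' @export
print.forward_operator <- function(x, ...) {
  cat(sprintf(
    "<forward_operator> %d modes, coupling %.2f, seed %d, grid %d^2 @ %.3g um\n",
    ncol(x$modes_ortho), x$coupling_strength, x$seed, x$grid$n_pixels,
    x$grid$pitch))
  invisible(x)
}
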