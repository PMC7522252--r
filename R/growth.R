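#' Genetic root growth traits
#'
#' Collects the plant-side inputs of the growth model: the axis
#' emergence schedule, age-dependent maximum elongation tables per root
#' order, branching geometry and timing, and the growth-direction
#' weights.
#'
#' @param axes_table data frame `age` (day), `rate` (cm/day): maximum
#'   elongation of first-order axes versus age (piecewise linear,
#'   constant beyond the table ends). Axis elongation decreases with
#'   age.
#' @param lateral_table same layout for laterals (constant by default).
#' @param branching_angle insertion angle between a lateral and its
#'   parent (degrees), default 32.55.
#' @param spacing arc-length distance between branch points (cm),
#'   default 0.3.
#' @param tip_delay branching delay (day), default 2.1. The first
#'   lateral of a root germinates `tip_delay` after the root itself
#'   (the trait as measured); later branch points activate `tip_delay`
#'   after the parent tip passes them (see `first_lateral_from_birth`).
#' @param first_lateral_from_birth logical; anchor the first branch
#'   point's delay at the parent root's birth (default `TRUE`).
#' @param max_order deepest branching order allowed (1 = axes only).
#' @param W_g geotropism weight (-), default 0.1 (calibrated).
#' @param W_r penetration-resistance-gradient weight (-), default 0.45
#'   (calibrated).
#' @param delta maximum random deviation angle (degrees), default 35
#'   (calibrated).
#' @param W_oi initial obstacle-history weight, default 5 (calibrated).
#' @param kappa recovery/contact time ratio, default 2 (calibrated).
#' @param contact_threshold tip-obstacle contact distance (cm). The
#'   default `NULL` resolves at run time to
#'   `max(root radius, 1.5 * smallest element edge)`: the detection
#'   band must cover the one-to-two element wide zone over which the
#'   discrete resistance-gradient acts, otherwise the gradient term
#'   deflects tips before contact can ever be registered.
#' @param grad_tol gradient magnitude below which the resistance term is
#'   dropped (kPa/cm).
#' @return An object of class `growth_traits`.
#' @export
growth_traits <- function(axes_table = data.frame(
                            age = c(0, 1, 2, 3, 3.5, 6),
                            rate = c(2.0, 1.6, 1.2, 0.8, 0.6, 0.4)),
                          lateral_table = data.frame(
                            age = c(0, 2), rate = c(0.4, 0.4)),
                          branching_angle = 32.55, spacing = 0.3,
                          tip_delay = 2.1,
                          first_lateral_from_birth = TRUE,
                          max_order = 2L,
                          W_g = 0.1, W_r = 0.45, delta = 35,
                          W_oi = 5, kappa = 2,
                          contact_threshold = NULL,
                          grad_tol = 1e-8) {
  stopifnot(W_g >= 0, W_r >= 0, delta >= 0, delta < 90,
            spacing > 0, tip_delay >= 0, max_order >= 1)
  if (any(axes_table$rate < 0) || any(lateral_table$rate < 0))
    stop("elongation rates must be non-negative")
  structure(list(axes_table = axes_table, lateral_table = lateral_table,
                 branching_angle = branching_angle, spacing = spacing,
                 tip_delay = tip_delay,
                 first_lateral_from_birth = isTRUE(first_lateral_from_birth),
                 max_order = as.integer(max_order),
                 W_g = W_g, W_r = W_r, delta = delta,
                 W_oi = W_oi, kappa = kappa,
                 contact_threshold = contact_threshold,
                 grad_tol = grad_tol),
            class = "growth_traits")
}

#' Maximum elongation rate at a given root age
#'
#' @param traits a [growth_traits()].
#' @param order root order (1 = axis).
#' @param age root age (day).
#' @return `E_max` (cm/day), linearly interpolated in the order's table.
#' @export
e_max_at <- function(traits, order, age) {
  tab <- if (order <= 1) traits$axes_table else traits$lateral_table
  if (nrow(tab) == 1) return(rep(tab$rate, length(age)))
  stats::approx(tab$age, tab$rate, xout = age, rule = 2)$y
}

#' Sample the random deviation angle
#'
#' Uniform on `[-delta, +delta]` degrees, drawn from R's global RNG
#' stream so seeded runs are reproducible.
#'
#' @param delta maximum deviation (degrees, >= 0).
#' @param n number of draws.
#' @return Angles in degrees.
#' @export
sample_deviation <- function(delta, n = 1) {
  stopifnot(delta >= 0)
  if (delta == 0) return(rep(0, n))
  stats::runif(n, -delta, delta)
}

#' Rotate a 2D vector
#'
#' @param v numeric length-2.
#' @param angle_deg rotation angle (degrees, counter-clockwise).
#' @return Rotated vector.
#' @export
rotate2 <- function(v, angle_deg) {
  th <- angle_deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2],
    sin(th) * v[1] + cos(th) * v[2])
}

#' Weighted growth-direction update
#'
#' `d_new = normalize(w_hist * H + W_g * g + W_r * u)` where `H` is the
#' (rotated) previous direction or, during recovery, the supplied
#' history vector, and `u` is the unit vector opposite the penetration
#' resistance gradient (zero when the gradient is below `grad_tol`).
#'
#' @param d_old unit previous direction.
#' @param g unit gravity direction.
#' @param gradR resistance gradient (kPa/cm), numeric length-2.
#' @param W_g,W_r weights of gravity and resistance-gradient terms.
#' @param delta_sample deviation angle for this step (degrees).
#' @param w_hist weight on the history term (1 outside recovery, `W_o`
#'   during recovery).
#' @param hist optional explicit history vector replacing the rotated
#'   `d_old` (used during recovery).
#' @param grad_tol gradient magnitude tolerance.
#' @return Unit direction, numeric length-2.
#' @export
growth_direction <- function(d_old, g, gradR = c(0, 0), W_g, W_r,
                             delta_sample = 0, w_hist = 1, hist = NULL,
                             grad_tol = 1e-8) {
  gn <- sqrt(sum(gradR^2))
  u <- if (gn < grad_tol) c(0, 0) else -gradR / gn
  H <- if (is.null(hist)) rotate2(d_old, delta_sample) else hist
  v <- w_hist * H + W_g * g + W_r * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12)
    stop(sprintf(
      "degenerate growth direction: resultant ~0 (w_hist=%g, W_g=%g, W_r=%g)",
      w_hist, W_g, W_r))
  v / nv
}

#' Penetration resistance field on the grid elements
#'
#' Computes `R` per element from the element-mean pressure head, the
#' material's effective saturation and its bulk density.
#'
#' @param grid a [soil_grid()].
#' @param state a `water_state`.
#' @param materials list of [van_genuchten()] materials.
#' @param elem_mat integer material index per element.
#' @return Numeric vector of `R` (kPa) per element.
#' @export
resistance_field <- function(grid, state, materials, elem_mat = NULL) {
  if (inherits(materials, "vg_soil")) materials <- list(materials)
  if (is.null(elem_mat)) elem_mat <- state$elem_mat
  if (is.null(elem_mat)) elem_mat <- rep(1L, grid$nelem)
  h_e <- rowMeans(matrix(state$h[grid$conn], ncol = 4))
  R <- numeric(grid$nelem)
  for (m in seq_along(materials)) {
    sel <- elem_mat == m
    if (!any(sel)) next
    soil <- materials[[m]]
    th <- theta_of_h(h_e[sel], soil)
    Se <- effective_saturation(th, soil)
    psi <- head_to_potential(h_e[sel])
    R[sel] <- penetration_resistance(psi, Se, soil$rho_b)
  }
  R
}

# central-difference gradient of an element-centred field; one-sided at
# the domain borders; returns nelem x 2 matrix
elem_gradient <- function(grid, field_e) {
  Fm <- matrix(field_e, grid$nx, grid$nz)
  gx <- Fm
  gz <- Fm
  nx <- grid$nx; nz <- grid$nz
  if (nx > 1) {
    gx[2:(nx - 1), ] <- (Fm[3:nx, , drop = FALSE] -
                           Fm[1:(nx - 2), , drop = FALSE]) / (2 * grid$dx)
    gx[1, ] <- (Fm[2, ] - Fm[1, ]) / grid$dx
    gx[nx, ] <- (Fm[nx, ] - Fm[nx - 1, ]) / grid$dx
  } else gx[] <- 0
  if (nz > 1) {
    gz[, 2:(nz - 1)] <- (Fm[, 3:nz, drop = FALSE] -
                           Fm[, 1:(nz - 2), drop = FALSE]) / (2 * grid$dz)
    gz[, 1] <- (Fm[, 2] - Fm[, 1]) / grid$dz
    gz[, nz] <- (Fm[, nz] - Fm[, nz - 1]) / grid$dz
  } else gz[] <- 0
  cbind(as.numeric(gx), as.numeric(gz))
}

# bilinear interpolation of an element-centred field at (x, z)
interp_elem <- function(grid, field_e, x, z) {
  xc <- pmin(pmax(x, grid$dx / 2), grid$width - grid$dx / 2)
  zc <- pmin(pmax(z, grid$dz / 2), grid$height - grid$dz / 2)
  i <- pmin(pmax(1L, as.integer(floor(xc / grid$dx - 0.5)) + 1L), grid$nx - 1L)
  j <- pmin(pmax(1L, as.integer(floor(zc / grid$dz - 0.5)) + 1L), grid$nz - 1L)
  if (grid$nx == 1L) i <- 1L
  if (grid$nz == 1L) j <- 1L
  tx <- if (grid$nx > 1) (xc - (i - 0.5) * grid$dx) / grid$dx else 0
  tz <- if (grid$nz > 1) (zc - (j - 0.5) * grid$dz) / grid$dz else 0
  i2 <- pmin(i + 1L, grid$nx)
  j2 <- pmin(j + 1L, grid$nz)
  e <- function(ii, jj) field_e[ii + (jj - 1L) * grid$nx]
  (1 - tz) * ((1 - tx) * e(i, j) + tx * e(i2, j)) +
    tz * ((1 - tx) * e(i, j2) + tx * e(i2, j2))
}

#' Penetration-resistance gradient at a point
#'
#' Finite-difference gradient of the elemental resistance field,
#' interpolated bilinearly at the given position; the zero vector is
#' returned when the gradient magnitude is below `tol`.
#'
#' @param grid a [soil_grid()].
#' @param R_elem elemental resistance field (kPa), e.g. from
#'   [resistance_field()].
#' @param x,z position (cm); must lie inside the domain.
#' @param tol magnitude tolerance (kPa/cm).
#' @return Numeric length-2 gradient (kPa/cm).
#' @export
resistance_gradient_at <- function(grid, R_elem, x, z, tol = 1e-8) {
  if (x < -1e-9 || x > grid$width + 1e-9 || z < -1e-9 ||
      z > grid$height + 1e-9)
    stop("position outside the grid domain")
  gr <- elem_gradient(grid, R_elem)
  g <- c(interp_elem(grid, gr[, 1], x, z),
         interp_elem(grid, gr[, 2], x, z))
  if (sqrt(sum(g^2)) < tol) c(0, 0) else g
}

# clip a step to the rectangular domain; returns list(p, hit)
clip_to_domain <- function(p0, p1, grid) {
  tmax <- 1
  d <- p1 - p0
  bounds <- c(0, grid$width, 0, grid$height)
  if (d[1] < 0) tmax <- min(tmax, (0 - p0[1]) / d[1])
  if (d[1] > 0) tmax <- min(tmax, (grid$width - p0[1]) / d[1])
  if (d[2] < 0) tmax <- min(tmax, (0 - p0[2]) / d[2])
  if (d[2] > 0) tmax <- min(tmax, (grid$height - p0[2]) / d[2])
  tmax <- max(0, min(1, tmax))
  list(p = p0 + tmax * d, hit = tmax < 1 - 1e-12)
}

# growth angle beta (degrees from horizontal; 90 = vertical)
beta_angle <- function(dx, dz) atan2(abs(dz), abs(dx)) * 180 / pi
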