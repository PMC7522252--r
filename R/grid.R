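#' Structured pseudo-2D soil grid
#'
#' Builds a structured, axis-aligned rectangular grid for the growth
#' plane (x horizontal, z vertical, z increasing upward, origin at the
#' domain bottom-left). Elements are rectangular prisms one element thick
#' in the out-of-plane direction.
#'
#' @param width,height domain extents in x and z (cm).
#' @param nx,nz number of elements in x and z.
#' @param thickness out-of-plane thickness (cm).
#'
#' @return An object of class `soil_grid` with node coordinates,
#'   element connectivity and precomputed finite-volume geometry.
#' @export
soil_grid <- function(width = 10, height = 10, nx = 40, nz = 40,
                      thickness = 0.2) {
  stopifnot(width > 0, height > 0, nx >= 1, nz >= 1, thickness > 0)
  dx <- width / nx
  dz <- height / nz
  xs <- seq(0, width, length.out = nx + 1)
  zs <- seq(0, height, length.out = nz + 1)
  nnx <- nx + 1L
  nnz <- nz + 1L
  nnode <- nnx * nnz
  # node id = i + (j-1)*nnx, i over x, j over z (bottom to top)
  node_x <- rep(xs, times = nnz)
  node_z <- rep(zs, each = nnx)
  nelem <- nx * nz
  ei <- rep(seq_len(nx), times = nz)
  ej <- rep(seq_len(nz), each = nx)
  n1 <- ei + (ej - 1L) * nnx        # bottom-left
  conn <- cbind(n1, n1 + 1L, n1 + nnx, n1 + nnx + 1L)
  elem_x <- (ei - 0.5) * dx
  elem_z <- (ej - 0.5) * dz
  v_elem <- dx * dz * thickness

  # node control volumes (quarter of each adjacent element)
  v_node <- numeric(nnode)
  for (k in 1:4) {
    tab <- tabulate(conn[, k], nbins = nnode)
    v_node <- v_node + tab * v_elem / 4
  }

  # finite-volume edges: node pairs with up to two adjacent elements
  # x-direction edges (flow along x)
  exi <- rep(seq_len(nx), times = nnz)
  exj <- rep(seq_len(nnz), each = nx)
  ex_a <- exi + (exj - 1L) * nnx
  ex_b <- ex_a + 1L
  ex_e1 <- ifelse(exj - 1L >= 1L & exj - 1L <= nz,
                  exi + (exj - 2L) * nx, NA_integer_)  # element below
  ex_e2 <- ifelse(exj >= 1L & exj <= nz,
                  exi + (exj - 1L) * nx, NA_integer_)  # element above
  ex_geom <- (dz / 2) * thickness / dx
  # z-direction edges (flow along z)
  ezi <- rep(seq_len(nnx), times = nz)
  ezj <- rep(seq_len(nz), each = nnx)
  ez_a <- ezi + (ezj - 1L) * nnx
  ez_b <- ez_a + nnx
  ez_e1 <- ifelse(ezi - 1L >= 1L & ezi - 1L <= nx,
                  (ezi - 1L) + (ezj - 1L) * nx, NA_integer_)  # left elem
  ez_e2 <- ifelse(ezi >= 1L & ezi <= nx,
                  ezi + (ezj - 1L) * nx, NA_integer_)         # right elem
  ez_geom <- (dx / 2) * thickness / dz

  edges <- list(
    a = c(ex_a, ez_a), b = c(ex_b, ez_b),
    e1 = c(ex_e1, ez_e1), e2 = c(ex_e2, ez_e2),
    geom = c(rep(ex_geom, length(ex_a)), rep(ez_geom, length(ez_a))))
  edges$dzab <- node_z[edges$b] - node_z[edges$a]

  structure(list(width = width, height = height, nx = nx, nz = nz,
                 dx = dx, dz = dz, thickness = thickness,
                 xs = xs, zs = zs, nnode = nnode, nelem = nelem,
                 node_x = node_x, node_z = node_z,
                 conn = conn, elem_x = elem_x, elem_z = elem_z,
                 v_elem = v_elem, v_node = v_node, edges = edges),
            class = "soil_grid")
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf(
    "soil_grid: %g x %g cm, %d x %d elements (dx=%g, dz=%g), thickness %g cm\n",
    x$width, x$height, x$nx, x$nz, x$dx, x$dz, x$thickness))
  invisible(x)
}

#' Locate the element containing a point
#'
#' @param grid a [soil_grid()].
#' @param x,z coordinates (cm); vectorised.
#' @return Integer element ids; error if any point is outside the domain.
#' @export
locate_element <- function(grid, x, z) {
  eps <- 1e-9
  if (any(x < -eps | x > grid$width + eps | z < -eps | z > grid$height + eps))
    stop("point outside the grid domain")
  i <- pmin(pmax(1L, as.integer(ceiling(x / grid$dx - 1e-12))), grid$nx)
  j <- pmin(pmax(1L, as.integer(ceiling(z / grid$dz - 1e-12))), grid$nz)
  i + (j - 1L) * grid$nx
}

#' Bilinear interpolation of a nodal field
#'
#' @param grid a [soil_grid()].
#' @param field numeric vector over grid nodes.
#' @param x,z coordinates (cm); vectorised.
#' @return Interpolated values.
#' @export
interp_nodal <- function(grid, field, x, z) {
  e <- locate_element(grid, x, z)
  i <- ((e - 1L) %% grid$nx) + 1L
  j <- ((e - 1L) %/% grid$nx) + 1L
  x0 <- (i - 1) * grid$dx
  z0 <- (j - 1) * grid$dz
  tx <- pmin(pmax((x - x0) / grid$dx, 0), 1)
  tz <- pmin(pmax((z - z0) / grid$dz, 0), 1)
  nnx <- grid$nx + 1L
  n1 <- i + (j - 1L) * nnx
  f1 <- field[n1]; f2 <- field[n1 + 1L]
  f3 <- field[n1 + nnx]; f4 <- field[n1 + nnx + 1L]
  (1 - tz) * ((1 - tx) * f1 + tx * f2) + tz * ((1 - tx) * f3 + tx * f4)
}

#' Per-node material mixing weights
#'
#' Each node's storage mixes the retention curves of its adjacent
#' elements' materials, weighted by quarter-element volumes, so nodes on
#' a material interface conserve mass for both materials.
#'
#' @param grid a [soil_grid()].
#' @param elem_mat integer material index per element.
#' @param nmat number of materials.
#' @return A `nnode x nmat` matrix of volume fractions (rows sum to 1).
#' @keywords internal
node_material_weights <- function(grid, elem_mat, nmat) {
  w <- matrix(0, grid$nnode, nmat)
  add <- grid$v_elem / 4
  for (k in 1:4) {
    for (m in seq_len(nmat)) {
      sel <- elem_mat == m
      if (any(sel)) {
        tab <- tabulate(grid$conn[sel, k], nbins = grid$nnode)
        w[, m] <- w[, m] + tab * add
      }
    }
  }
  w / rowSums(w)
}

#' Hydrostatic initial water state
#'
#' Sets `h(z) = -(z - water_table_z)` so the total head `h + z` is
#' uniform: a no-flow equilibrium with the water table at
#' `water_table_z`.
#'
#' @param grid a [soil_grid()].
#' @param materials list of [van_genuchten()] materials.
#' @param elem_mat integer material index per element (default all 1).
#' @param water_table_z elevation of the water table (cm), default the
#'   domain bottom.
#' @return An object of class `water_state` with nodal pressure head,
#'   water content, conductivity and an all-zero elemental sink.
#' @export
hydrostatic_init <- function(grid, materials, elem_mat = NULL,
                             water_table_z = 0) {
  if (inherits(materials, "vg_soil")) materials <- list(materials)
  if (is.null(elem_mat)) elem_mat <- rep(1L, grid$nelem)
  if (water_table_z < 0 || water_table_z > grid$height)
    stop("water table outside the domain")
  h <- -(grid$node_z - water_table_z)
  mixw <- node_material_weights(grid, elem_mat, length(materials))
  st <- list(time = 0, h = h,
             theta = mixed_theta(h, materials, mixw),
             K = mixed_field(h, materials, mixw, k_of_h),
             sink = rep(0, grid$nelem),
             picard_iters = 0L,
             mix_weights = mixw, elem_mat = elem_mat)
  class(st) <- "water_state"
  st
}

# volume-weighted nodal water content across adjacent materials
mixed_theta <- function(h, materials, mixw) {
  mixed_field(h, materials, mixw, theta_of_h)
}

mixed_field <- function(h, materials, mixw, fn) {
  out <- numeric(length(h))
  for (m in seq_along(materials))
    out <- out + mixw[, m] * fn(h, materials[[m]])
  out
}

#' @export
print.water_state <- function(x, ...) {
  cat(sprintf(
    "water_state @ t=%.4g day: h in [%.4g, %.4g] cm, theta in [%.4g, %.4g]\n",
    x$time, min(x$h), max(x$h), min(x$theta), max(x$theta)))
  invisible(x)
}
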