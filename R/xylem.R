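#' Solve steady water flow in the root xylem network
#'
#' Each root segment carries axial Darcy flow
#' `J_x = -K_x (dh_x/dl + dz/dl)` between its proximal and distal nodes
#' and exchanges water radially with the soil,
#' `q_r = L_r (h_s - h_x)`, `J_r = 2 pi r l_seg q_r`. Xylem storage is
#' neglected, so node-wise flow balance plus a prescribed collar
#' (transpiration) outflow determines the xylem heads. By construction
#' the sum of radial inflows equals the collar flux at machine
#' precision.
#'
#' @param segments data frame with one row per segment: columns `seg`
#'   (integer id), `parent_seg` (id of the parent segment, 0 for
#'   segments attached to the collar), `z1` (distal-end elevation, cm),
#'   `len` (cm), plus optionally per-segment `K_x`, `L_r`, `radius`.
#' @param h_soil soil pressure head at each segment (cm).
#' @param collar_flux transpiration demand at the collar (cm^3/day,
#'   non-negative).
#' @param collar_z elevation of the collar node (cm).
#' @param K_x axial conductance per unit segment length (cm^3/day),
#'   used where the table has no `K_x` column.
#' @param L_r radial conductivity (cm/day), likewise.
#' @param radius root radius (cm), likewise.
#' @param h_collar_min water-stress switch (cm): when satisfying the
#'   flux demand would pull the collar head below this limit, the
#'   collar is clamped to it and the actual (reduced) flux is returned.
#'   Default `-Inf` disables the switch.
#' @return A list with per-segment vectors `h_x` (xylem pressure head at
#'   the distal node, cm), `q_r` (radial flux density, cm/day), `J_r`
#'   (radial volumetric flow, cm^3/day), `J_x` (axial flow from parent
#'   to segment, cm^3/day), and scalars `h_collar`, `collar_flux`.
#' @export
solve_xylem <- function(segments, h_soil, collar_flux, collar_z,
                        K_x = 4.32e-2, L_r = 1.73e-4, radius = 0.03,
                        h_collar_min = -Inf) {
  n <- nrow(segments)
  if (n == 0) stop("empty root system")
  if (collar_flux < 0) stop("collar flux must be >= 0")
  stopifnot(length(h_soil) == n)
  id <- segments$seg
  pos <- match(segments$parent_seg, id)   # NA -> collar child
  if (any(is.na(pos) & segments$parent_seg != 0))
    stop("disconnected segment(s): parent id not present: ",
         paste(segments$parent_seg[is.na(pos) & segments$parent_seg != 0],
               collapse = ", "))
  kx <- if ("K_x" %in% names(segments)) segments$K_x else rep(K_x, n)
  lr <- if ("L_r" %in% names(segments)) segments$L_r else rep(L_r, n)
  rr <- if ("radius" %in% names(segments)) segments$radius else rep(radius, n)
  len <- segments$len
  if (any(len <= 0)) stop("segment lengths must be positive")
  g_ax <- kx / len                       # axial conductance (cm^3/day/cm)
  c_rad <- 2 * pi * rr * len * lr        # radial conductance
  if (all(c_rad <= 0)) stop("singular xylem system: all radial conductances zero")

  # nodes: 1..n = segment distal ends, n+1 = collar
  collar <- n + 1L
  pnode <- ifelse(is.na(pos) | segments$parent_seg == 0, collar, pos)
  nn <- n + 1L
  ii <- c(seq_len(n), pnode, seq_len(n), pnode, seq_len(n))
  jj <- c(seq_len(n), pnode, pnode, seq_len(n), seq_len(n))
  xx <- c(g_ax, g_ax, -g_ax, -g_ax, c_rad)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  z_node <- c(segments$z1, collar_z)
  H_soil <- h_soil + segments$z1         # total soil head at the segment
  rhs <- c(c_rad * H_soil, -collar_flux)
  H <- as.numeric(Matrix::solve(A, rhs))
  actual_flux <- collar_flux
  if (is.finite(h_collar_min) && H[collar] - collar_z < h_collar_min) {
    # water stress: clamp the collar head and accept the reduced flux
    H_fix <- h_collar_min + collar_z
    Ar <- A[seq_len(n), seq_len(n), drop = FALSE]
    rr <- c_rad * H_soil
    coupled <- which(pnode == collar)
    rr[coupled] <- rr[coupled] + g_ax[coupled] * H_fix
    Hr <- as.numeric(Matrix::solve(Ar, rr))
    H <- c(Hr, H_fix)
    actual_flux <- sum(g_ax[coupled] * (H[coupled] - H_fix))
  }
  J_r <- c_rad * (H_soil - H[seq_len(n)])
  J_x <- g_ax * (H[pnode] - H[seq_len(n)])  # flow from parent into segment
  list(h_x = H[seq_len(n)] - z_node[seq_len(n)],
       q_r = J_r / (2 * pi * rr * len),
       J_r = J_r, J_x = J_x,
       h_collar = H[collar] - collar_z,
       collar_flux = actual_flux,
       demand = collar_flux,
       stressed = actual_flux < collar_flux - 1e-12)
}

#' Distribute radial root uptake onto the soil grid
#'
#' Each segment's radial volumetric flow `J_r` is spread over the soil
#' elements crossed by its midline, proportionally to the in-element
#' length, and converted to a volumetric sink density (1/day).
#'
#' @param segments data frame with columns `x0`, `z0`, `x1`, `z1`, `len`.
#' @param grid a [soil_grid()].
#' @param J_r per-segment radial volumetric flow (cm^3/day).
#' @return Elemental sink `S` (1/day) with
#'   `sum(S * v_elem) == sum(J_r)`.
#' @export
assemble_sink <- function(segments, grid, J_r) {
  S <- rep(0, grid$nelem)
  if (nrow(segments) == 0) return(S)
  stopifnot(length(J_r) == nrow(segments))
  for (s in seq_len(nrow(segments))) {
    parts <- segment_cell_lengths(grid, segments$x0[s], segments$z0[s],
                                  segments$x1[s], segments$z1[s])
    if (nrow(parts) == 0)
      stop("segment ", s, " lies outside the grid")
    S[parts$elem] <- S[parts$elem] +
      J_r[s] * parts$frac / grid$v_elem
  }
  S
}

#' Assemble the implicit root-uptake exchange on the soil grid
#'
#' Distributes each segment's radial conductance
#' `c = 2 pi r l_seg L_r` and its load `c * h_x` over the soil elements
#' crossed by the segment midline, proportionally to in-element length.
#' Passing the result to [richards_step()] as `sink_linear` makes the
#' uptake `c * (h - h_x)` implicit in the soil solve, so extraction
#' self-limits as an element dries toward the xylem head.
#'
#' @param segments data frame with columns `x0`, `z0`, `x1`, `z1`.
#' @param grid a [soil_grid()].
#' @param c_rad per-segment radial conductance (cm^3/day per cm head).
#' @param h_x per-segment xylem pressure head (cm).
#' @return List with per-element vectors `coef` and `load`.
#' @export
assemble_sink_exchange <- function(segments, grid, c_rad, h_x) {
  coef <- load <- rep(0, grid$nelem)
  if (nrow(segments) == 0) return(list(coef = coef, load = load))
  stopifnot(length(c_rad) == nrow(segments),
            length(h_x) == nrow(segments))
  for (s in seq_len(nrow(segments))) {
    parts <- segment_cell_lengths(grid, segments$x0[s], segments$z0[s],
                                  segments$x1[s], segments$z1[s])
    coef[parts$elem] <- coef[parts$elem] + c_rad[s] * parts$frac
    load[parts$elem] <- load[parts$elem] + c_rad[s] * parts$frac * h_x[s]
  }
  list(coef = coef, load = load)
}

# split a segment by the grid lines; returns element ids and length
# fractions (summing to 1)
segment_cell_lengths <- function(grid, x0, z0, x1, z1) {
  eps <- 1e-9
  if (min(x0, x1) < -eps || max(x0, x1) > grid$width + eps ||
      min(z0, z1) < -eps || max(z0, z1) > grid$height + eps)
    stop("segment endpoint outside the grid domain")
  ts <- c(0, 1)
  if (abs(x1 - x0) > eps) {
    tx <- (grid$xs - x0) / (x1 - x0)
    ts <- c(ts, tx[tx > eps & tx < 1 - eps])
  }
  if (abs(z1 - z0) > eps) {
    tz <- (grid$zs - z0) / (z1 - z0)
    ts <- c(ts, tz[tz > eps & tz < 1 - eps])
  }
  ts <- sort(unique(ts))
  mids <- (ts[-length(ts)] + ts[-1]) / 2
  fr <- ts[-1] - ts[-length(ts)]
  xm <- x0 + mids * (x1 - x0)
  zm <- z0 + mids * (z1 - z0)
  keep <- fr > eps
  data.frame(elem = locate_element(grid, xm[keep], zm[keep]),
             frac = fr[keep] / sum(fr[keep]))
}
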