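#' One transient step of unsaturated water flow
#'
#' Advances the Richards equation `d(theta)/dt = div(K grad(h+z)) - S` on
#' a structured grid by `dt` days, using a node-centred finite-volume
#' discretisation (mass-lumped bilinear elements) and the
#' mass-conservative mixed-form Picard linearisation. All outer faces are
#' no-flux unless `dirichlet_bottom` pins `h = 0` on the bottom edge.
#'
#' A step is accepted only when both the head increment and the global
#' nonlinear mass residual fall below tolerance; otherwise the step is
#' retried with halved substeps down to `dt / 2^max_halvings`, after
#' which a step-failure error (condition class `rhizogrow_step_error`)
#' carrying residual diagnostics is signalled.
#'
#' @param grid a [soil_grid()].
#' @param state a `water_state` (see [hydrostatic_init()]).
#' @param materials list of [van_genuchten()] materials.
#' @param sink elemental sink `S` (1/day, positive = uptake), length
#'   `grid$nelem`; `NULL` means zero.
#' @param dt time step (day), must be positive.
#' @param elem_mat integer material index per element; defaults to the
#'   map stored in `state`.
#' @param control list of solver controls: `tol_h` (cm, default 1e-6),
#'   `tol_mass` (relative, default 1e-9), `max_iter` (default 50),
#'   `max_halvings` (default 6), `dirichlet_bottom` (default FALSE).
#' @param sink_linear optional implicit root-uptake exchange, a list
#'   with per-element vectors `coef` (cm^3/day per cm head) and `load`
#'   (cm^3/day): the extraction from an element is
#'   `coef * h - load = coef * (h - h_x)`, evaluated implicitly so
#'   uptake self-limits as the element dries toward the xylem head.
#'   See [assemble_sink_exchange()].
#' @return The advanced `water_state`.
#' @export
richards_step <- function(grid, state, materials, sink = NULL, dt,
                          elem_mat = NULL, control = list(),
                          sink_linear = NULL) {
  if (inherits(materials, "vg_soil")) materials <- list(materials)
  if (is.null(elem_mat)) elem_mat <- state$elem_mat
  if (is.null(elem_mat)) elem_mat <- rep(1L, grid$nelem)
  if (is.null(sink)) sink <- rep(0, grid$nelem)
  stopifnot(length(sink) == grid$nelem, dt > 0)
  ctl <- utils::modifyList(list(tol_h = 1e-6, tol_mass = 1e-9,
                                tol_mass_abs = 1e-7,
                                max_iter = 50L, max_halvings = 6L,
                                h_stress_on = -15000, h_stress_off = -25000,
                                dirichlet_bottom = FALSE), control)

  mixw <- state$mix_weights
  if (is.null(mixw) || !identical(state$elem_mat, elem_mat))
    mixw <- node_material_weights(grid, elem_mat, length(materials))

  ed <- grid$edges
  # material index of each edge-adjacent element
  ed$mat1 <- ifelse(is.na(ed$e1), NA_integer_, elem_mat[ed$e1])
  ed$mat2 <- ifelse(is.na(ed$e2), NA_integer_, elem_mat[ed$e2])

  # nodal volumetric extraction rate (cm^3/day): quarter of each element
  to_nodes <- function(vals_e) {
    out <- numeric(grid$nnode)
    for (k in 1:4)
      out <- out + tabulate_weighted(grid$conn[, k], vals_e / 4,
                                     grid$nnode)
    out
  }
  q_node <- to_nodes(sink * grid$v_elem)
  lin_coef <- lin_load <- numeric(grid$nnode)
  if (!is.null(sink_linear)) {
    lin_coef <- to_nodes(sink_linear$coef)
    lin_load <- to_nodes(sink_linear$load)
  }

  remaining <- dt
  sub_dt <- dt
  halvings <- 0L
  h <- state$h
  theta <- state$theta
  t_now <- state$time
  iters_total <- 0L

  while (remaining > 1e-15) {
    step_dt <- min(sub_dt, remaining)
    res <- picard_solve(grid, ed, h, theta, materials, mixw, q_node,
                        lin_coef, lin_load, step_dt, ctl)
    if (!res$converged) {
      halvings <- halvings + 1L
      if (halvings > ctl$max_halvings) {
        cond <- structure(
          class = c("rhizogrow_step_error", "error", "condition"),
          list(message = sprintf(
                 paste0("Richards step failed to converge: dt=%g day after %d",
                        " halvings (max |dh|=%.3g cm, mass residual=%.3g cm^3)"),
                 step_dt, halvings - 1L, res$dh, res$mass_err),
               call = sys.call(-1),
               diagnostics = list(dt = step_dt, dh = res$dh,
                                  mass_err = res$mass_err,
                                  time = t_now)))
        stop(cond)
      }
      sub_dt <- sub_dt / 2
      next
    }
    h <- res$h
    theta <- res$theta
    t_now <- t_now + step_dt
    remaining <- remaining - step_dt
    iters_total <- iters_total + res$iters
  }

  state$time <- t_now
  state$h <- h
  state$theta <- theta
  state$K <- mixed_field(h, materials, mixw, k_of_h)
  state$sink <- sink
  state$picard_iters <- iters_total
  state$mix_weights <- mixw
  state$elem_mat <- elem_mat
  state
}

# scatter-add helper: sum w by integer index into nbins slots
tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# one sub-step: mixed-form Picard iteration (Celia scheme)
picard_solve <- function(grid, ed, h_old, theta_old, materials, mixw,
                         q_node, lin_coef, lin_load, dt, ctl) {
  hk <- h_old
  vn <- grid$v_node
  bottom_nodes <- which(grid$node_z <= 0)
  # scale for the mass-balance check: relative to the sink volume over
  # the step, with an absolute floor (tol_mass_abs) for vanishing sinks
  # and near-dry conditions
  q_scale0 <- abs(sum(q_node)) + abs(sum(lin_coef * h_old - lin_load))
  mass_tol <- max(ctl$tol_mass * q_scale0 * dt, ctl$tol_mass_abs)
  dh <- Inf
  mass_err <- Inf
  omega <- 1           # adaptive under-relaxation
  dh_prev <- Inf
  for (it in seq_len(ctl$max_iter)) {
    h_edge <- (hk[ed$a] + hk[ed$b]) / 2
    tt <- edge_conductivity(h_edge, ed, materials) * ed$geom

    theta_k <- mixed_theta(hk, materials, mixw)
    cap_k <- mixed_field(hk, materials, mixw, capacity_of_h)

    # capacity floor regularises the iteration matrix in saturated or
    # extremely dry nodes; the converged equation uses the true theta(h)
    diag_m <- vn * pmax(cap_k, 1e-12) / dt
    # Feddes-type dryness reduction: extraction shuts down linearly
    # between h_stress_on and h_stress_off so the sink stays feasible
    # when cells approach residual water content
    alpha <- pmin(1, pmax(0, (hk - ctl$h_stress_off) /
                               (ctl$h_stress_on - ctl$h_stress_off)))
    q_eff <- ifelse(q_node > 0, q_node * alpha, q_node)
    # Laplacian: (A h)_i = sum_edges T (h_i - h_j)
    ii <- c(ed$a, ed$b, ed$a, ed$b)
    jj <- c(ed$a, ed$b, ed$b, ed$a)
    xx <- c(tt, tt, -tt, -tt)
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(grid$nnode, grid$nnode))
    grav <- tabulate_weighted(ed$a, tt * ed$dzab, grid$nnode) -
      tabulate_weighted(ed$b, tt * ed$dzab, grid$nnode)
    rhs <- diag_m * hk - vn * (theta_k - theta_old) / dt + grav -
      q_eff + lin_load
    Asys <- A + Matrix::Diagonal(grid$nnode, diag_m + lin_coef)
    if (isTRUE(ctl$dirichlet_bottom)) {
      Asys <- as(Asys, "CsparseMatrix")
      for (bn in bottom_nodes) {
        Asys[bn, ] <- 0
        Asys[bn, bn] <- 1
        rhs[bn] <- 0
      }
    }
    h_new <- as.numeric(Matrix::solve(Asys, rhs))
    dh_raw <- max(abs(h_new - hk))
    if (dh_raw > dh_prev) omega <- max(omega / 2, 0.1)
    else omega <- min(1, omega * 1.25)
    dh_prev <- dh_raw
    h_new <- hk + omega * (h_new - hk)
    # physical head bounds guard against runaway iterates in dry soil
    h_new <- pmin(pmax(h_new, -1e6), 1e4)
    dh <- max(abs(h_new - hk))
    hk <- h_new
    # global nonlinear mass residual of the accepted iterate
    theta_new <- mixed_theta(hk, materials, mixw)
    alpha_new <- pmin(1, pmax(0, (hk - ctl$h_stress_off) /
                                   (ctl$h_stress_on - ctl$h_stress_off)))
    q_fin <- ifelse(q_node > 0, q_node * alpha_new, q_node) +
      lin_coef * hk - lin_load
    mass_err <- abs(sum(vn * (theta_new - theta_old)) + sum(q_fin) * dt)
    if (isTRUE(ctl$dirichlet_bottom)) mass_err <- 0  # open boundary
    if (dh < ctl$tol_h && mass_err <= mass_tol) {
      return(list(converged = TRUE, h = hk, theta = theta_new, iters = it,
                  dh = dh, mass_err = mass_err))
    }
  }
  list(converged = FALSE, h = hk, theta = mixed_theta(hk, materials, mixw),
       iters = ctl$max_iter, dh = dh, mass_err = mass_err)
}

# edge conductivity: mean over the (up to two) adjacent elements, each
# evaluated with its own material's K(h) at the edge-mean head
edge_conductivity <- function(h_edge, ed, materials) {
  kacc <- numeric(length(h_edge))
  cnt <- numeric(length(h_edge))
  for (side in 1:2) {
    mat_ids <- if (side == 1) ed$mat1 else ed$mat2
    ok <- !is.na(mat_ids)
    if (!any(ok)) next
    for (m in seq_along(materials)) {
      sel <- ok & !is.na(mat_ids) & mat_ids == m
      if (any(sel)) {
        kacc[sel] <- kacc[sel] + k_of_h(h_edge[sel], materials[[m]])
        cnt[sel] <- cnt[sel] + 1
      }
    }
  }
  kacc / pmax(cnt, 1)
}

#' Total water volume held in the grid
#'
#' @param grid a [soil_grid()].
#' @param state a `water_state`.
#' @return Water volume (cm^3), the node-volume weighted sum of theta.
#' @export
water_volume <- function(grid, state) sum(grid$v_node * state$theta)
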