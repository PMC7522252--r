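#' Default run configuration
#'
#' Returns the full nested configuration of a wheat-like growth run in a
#' 10 x 10 cm pseudo-2D chamber: calibration substrate parameters,
#' xylem conductances, a 0.2 cm^3/day collar transpiration flux, a
#' five-axis emergence schedule, and the calibrated growth traits
#' (branching angle 32.55 deg, spacing 0.3 cm, tip delay 2.1 day,
#' W_g = 0.1, W_r = 0.45, delta = 35 deg, W_oi = 5, kappa = 2).
#'
#' @return A nested configuration list understood by [simulate_rsa()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    domain = list(width = 10, height = 10, nx = 40, nz = 40,
                  thickness = 0.2),
    substrate = list(theta_r = 0.06, theta_s = 0.41, alpha = 0.03,
                     n = 2.51, K_s = 10.24, l_pore = 0.5, rho_b = 1.2),
    water = list(coupled = TRUE, water_table_z = 0,
                 dirichlet_bottom = FALSE, collar_flux = 0.2,
                 h_collar_min = -15000,
                 tol_h = 1e-6, max_iter = 50L, max_halvings = 6L),
    root_hydraulics = list(K_x = 4.32e-2, L_r = 1.73e-4, radius = 0.03),
    seed_pos = c(5, 9.5),
    schedule = data.frame(time = c(0, 0.5, 1, 1.5, 2),
                          orientation = c(90, 60, 120, 45, 135)),
    traits = list(),
    obstacles = list(),
    time = list(t_end = 6, dT = 0.05, output_dt = 0.5),
    out_dir = NULL
  )
}

# deep-merge user configuration into the defaults
merge_config <- function(user) {
  cfg <- default_config()
  if (is.null(user)) return(cfg)
  deep <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.data.frame(base[[nm]]) && !is.data.frame(over[[nm]]) &&
          !is.null(names(over[[nm]])))
        base[[nm]] <- deep(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  deep(cfg, user)
}

#' Read a run configuration file
#'
#' Accepts JSON or YAML; missing entries fall back to
#' [default_config()]. The `schedule` entry may be given as a list of
#' `{time, orientation}` records, and `obstacles` as a list of
#' `{center, length, width, eta, rho_b, K_s}` records.
#'
#' @param path file path (`.json`, `.yaml`, `.yml`).
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  if (!is.null(raw$schedule) && !is.data.frame(raw$schedule)) {
    sc <- raw$schedule
    raw$schedule <- data.frame(
      time = vapply(sc, function(s) as.numeric(s$time), 0),
      orientation = vapply(sc, function(s) as.numeric(s$orientation), 0))
  }
  if (!is.null(raw$seed_pos)) raw$seed_pos <- as.numeric(unlist(raw$seed_pos))
  merge_config(raw)
}

# materialise obstacle specs into obstacle objects
build_obstacles <- function(specs) {
  lapply(specs, function(o) {
    if (inherits(o, "obstacle")) return(o)
    obstacle(center = as.numeric(unlist(o$center)),
             length = o$length %||% 2,
             width = o$width %||% 0.2,
             eta = o$eta %||% 0,
             rho_b = o$rho_b %||% 1.4,
             K_s = o$K_s %||% 5)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate root system architecture growth
#'
#' Runs the coupled growth model: per RSA step (fixed `dT`), axes emerge
#' on schedule, queued laterals activate, the soil water state advances
#' (Richards step with internally adaptive substeps), the xylem network
#' is solved against the collar transpiration flux, the uptake sink is
#' re-assembled, the penetration-resistance field is refreshed, and
#' every active tip elongates along the weighted growth direction with
#' obstacle contact/recovery handling. The run is fully reproducible
#' given `config$seed`.
#'
#' @param config nested configuration list (see [default_config()]);
#'   missing entries are defaulted.
#' @return An object of class `rsa_simulation`: the final `roots`,
#'   `segments` and `tips` tables, per-axis `tip_log` (time, position,
#'   direction, growth angle beta, contact phase, W_o), obstacle contact
#'   `episodes`, collar flux balance series, snapshots at the output
#'   times, and the final soil `water` state.
#' @export
simulate_rsa <- function(config = list()) {
  cfg <- merge_config(config)
  set.seed(cfg$seed)
  tr <- if (inherits(cfg$traits, "growth_traits")) cfg$traits
  else do.call(growth_traits, cfg$traits)

  dom <- cfg$domain
  grid <- soil_grid(dom$width, dom$height, dom$nx, dom$nz, dom$thickness)
  substrate <- do.call(van_genuchten, cfg$substrate)
  obstacles <- build_obstacles(cfg$obstacles)
  elem_mat <- rasterize_obstacles(obstacles, grid)
  materials <- obstacle_materials(substrate, obstacles)
  wctl <- list(tol_h = cfg$water$tol_h, max_iter = cfg$water$max_iter,
               max_halvings = cfg$water$max_halvings,
               dirichlet_bottom = cfg$water$dirichlet_bottom)
  for (nm in c("h_stress_on", "h_stress_off", "tol_mass", "tol_mass_abs"))
    if (!is.null(cfg$water[[nm]])) wctl[[nm]] <- cfg$water[[nm]]
  wstate <- hydrostatic_init(grid, materials, elem_mat,
                             cfg$water$water_table_z)
  coupled <- isTRUE(cfg$water$coupled)
  if (is.null(tr$contact_threshold))
    tr$contact_threshold <- max(cfg$root_hydraulics$radius,
                                1.5 * min(grid$dx, grid$dz))

  schedule <- cfg$schedule
  if (nrow(schedule) > 0 && is.unsorted(schedule$time))
    schedule <- schedule[order(schedule$time), ]
  seed_pos <- as.numeric(cfg$seed_pos)
  if (seed_pos[1] < 0 || seed_pos[1] > grid$width ||
      seed_pos[2] < 0 || seed_pos[2] > grid$height)
    stop("seed position outside the domain")

  t_end <- cfg$time$t_end
  dT <- cfg$time$dT
  out_dt <- cfg$time$output_dt %||% dT
  nsteps <- if (t_end <= 0) 0L else as.integer(round(t_end / dT))

  w <- new.env(parent = emptyenv())
  w$roots <- data.frame(root = integer(0), parent_root = integer(0),
                        attach_arc = numeric(0), attach_seg = integer(0),
                        birth = numeric(0), order = integer(0),
                        x0 = numeric(0), z0 = numeric(0),
                        dx0 = numeric(0), dz0 = numeric(0),
                        apdx = numeric(0), apdz = numeric(0),
                        n_bp = integer(0))
  w$tip <- data.frame(root = integer(0), x = numeric(0), z = numeric(0),
                      dx = numeric(0), dz = numeric(0), arc = numeric(0),
                      halted = logical(0), dt_pending = numeric(0))
  w$cs <- list()
  w$last_seg <- integer(0)
  nseg_cap <- 1024L
  w$seg <- data.frame(seg = integer(nseg_cap), root = integer(nseg_cap),
                      parent_seg = integer(nseg_cap),
                      x0 = numeric(nseg_cap), z0 = numeric(nseg_cap),
                      x1 = numeric(nseg_cap), z1 = numeric(nseg_cap),
                      len = numeric(nseg_cap), birth = numeric(nseg_cap),
                      order = integer(nseg_cap))
  w$nseg <- 0L
  w$queue <- data.frame(parent_root = integer(0), arc = numeric(0),
                        x = numeric(0), z = numeric(0),
                        pdx = numeric(0), pdz = numeric(0),
                        side = integer(0), attach_seg = integer(0),
                        t_created = numeric(0), t_activate = numeric(0),
                        order = integer(0), done = logical(0))
  g_vec <- c(0, -1)

  add_segment <- function(root, parent_seg, p0, p1, t, order) {
    if (w$nseg == nrow(w$seg)) {
      pad <- w$seg[rep(1L, nrow(w$seg)), ]
      pad[] <- lapply(pad, function(col) rep(col[1][NA], nrow(pad)))
      w$seg <- rbind(w$seg, pad)
    }
    w$nseg <- w$nseg + 1L
    w$seg[w$nseg, ] <- list(w$nseg, root, parent_seg, p0[1], p0[2],
                            p1[1], p1[2],
                            sqrt(sum((p1 - p0)^2)), t, order)
    w$nseg
  }
  seg_table <- function() w$seg[seq_len(w$nseg), , drop = FALSE]

  new_root <- function(parent_root, attach_arc, attach_seg, birth, order,
                       pos, dir, dt_pending, pdir = c(NA_real_, NA_real_)) {
    rid <- nrow(w$roots) + 1L
    w$roots[rid, ] <- list(rid, parent_root, attach_arc, attach_seg,
                           birth, order, pos[1], pos[2], dir[1], dir[2],
                           pdir[1], pdir[2], 0L)
    w$tip[rid, ] <- list(rid, pos[1], pos[2], dir[1], dir[2], 0,
                         FALSE, dt_pending)
    w$cs[[rid]] <- new_contact_state(tr$W_oi, tr$kappa)
    w$last_seg[rid] <- attach_seg
    rid
  }

  emerged <- rep(FALSE, nrow(schedule))
  snapshots <- list()
  tip_log <- list()
  collar_log <- list()
  next_out <- 0
  sink <- rep(0, grid$nelem)
  exchange <- NULL
  xylem <- NULL

  R_e <- resistance_field(grid, wstate, materials, elem_mat)
  gr_e <- elem_gradient(grid, R_e)

  take_snapshot <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<- list(
      time = t, roots = w$roots, segments = seg_table(),
      tips = w$tip)
  }
  if (nrow(schedule) > 0 && any(schedule$time <= 0)) {
    for (a in which(schedule$time <= 0)) {
      emerged[a] <- TRUE
      o <- schedule$orientation[a] * pi / 180
      new_root(0L, 0, 0L, schedule$time[a], 1L, seed_pos,
               c(cos(o), -sin(o)), dT)
    }
  }
  take_snapshot(0)

  for (step in seq_len(nsteps)) {
    ts <- (step - 1) * dT
    te <- step * dT

    # axis emergence
    due <- which(!emerged & schedule$time < te - 1e-12)
    for (a in due) {
      emerged[a] <- TRUE
      o <- schedule$orientation[a] * pi / 180
      new_root(0L, 0, 0L, schedule$time[a], 1L, seed_pos,
               c(cos(o), -sin(o)), te - max(ts, schedule$time[a]))
    }

    # lateral activation
    if (nrow(w$queue) > 0) {
      act <- which(!w$queue$done & w$queue$t_activate < te - 1e-12 &
                     w$queue$order <= tr$max_order)
      for (qi in act) {
        q <- w$queue[qi, ]
        w$queue$done[qi] <- TRUE
        ldir <- rotate2(c(q$pdx, q$pdz), q$side * tr$branching_angle)
        new_root(q$parent_root, q$arc, q$attach_seg, q$t_activate,
                 q$order, c(q$x, q$z), ldir,
                 min(dT, te - q$t_activate), pdir = c(q$pdx, q$pdz))
      }
    }

    # soil water and xylem update
    if (coupled) {
      wstate <- richards_step(grid, wstate, materials, NULL, dT,
                              elem_mat, wctl, sink_linear = exchange)
      if (w$nseg > 0L) {
        segs <- seg_table()
        xm <- (segs$x0 + segs$x1) / 2
        zm <- (segs$z0 + segs$z1) / 2
        h_soil <- interp_nodal(grid, wstate$h, xm, zm)
        xylem <- solve_xylem(segs, h_soil, cfg$water$collar_flux,
                             seed_pos[2],
                             K_x = cfg$root_hydraulics$K_x,
                             L_r = cfg$root_hydraulics$L_r,
                             radius = cfg$root_hydraulics$radius,
                             h_collar_min = cfg$water$h_collar_min %||% -Inf)
        sink <- assemble_sink(segs, grid, xylem$J_r)
        c_rad <- 2 * pi * cfg$root_hydraulics$radius * segs$len *
          cfg$root_hydraulics$L_r
        exchange <- assemble_sink_exchange(segs, grid, c_rad, xylem$h_x)
        collar_log[[length(collar_log) + 1L]] <-
          data.frame(time = te, total_J_r = sum(xylem$J_r),
                     collar_flux = xylem$collar_flux,
                     demand = cfg$water$collar_flux,
                     stressed = xylem$stressed,
                     h_collar = xylem$h_collar)
      }
      R_e <- resistance_field(grid, wstate, materials, elem_mat)
      gr_e <- elem_gradient(grid, R_e)
    }

    # advance every active tip
    for (rid in w$roots$root) {
      if (w$tip$halted[rid]) next
      advance_one_tip(w, rid, ts, te, grid, wstate, R_e, gr_e,
                      obstacles, tr, g_vec, add_segment)
    }

    # per-step log of axis tips (for growth-angle trajectories)
    ax <- which(w$roots$order == 1L)
    if (length(ax) > 0) {
      tip_log[[length(tip_log) + 1L]] <- data.frame(
        time = te, root = w$tip$root[ax],
        x = w$tip$x[ax], z = w$tip$z[ax],
        dx = w$tip$dx[ax], dz = w$tip$dz[ax],
        beta = beta_angle(w$tip$dx[ax], w$tip$dz[ax]),
        phase = vapply(ax, function(r) w$cs[[r]]$phase, ""),
        W_o = vapply(ax, function(r) w_o_weight(w$cs[[r]], ts), 0))
    }

    if (te >= next_out + out_dt - 1e-9) {
      take_snapshot(te)
      next_out <- next_out + out_dt
    }
  }

  # final xylem solve so the reported solution matches the final geometry
  if (coupled && w$nseg > 0L) {
    segs <- seg_table()
    h_soil <- interp_nodal(grid, wstate$h, (segs$x0 + segs$x1) / 2,
                           (segs$z0 + segs$z1) / 2)
    xylem <- solve_xylem(segs, h_soil, cfg$water$collar_flux, seed_pos[2],
                         K_x = cfg$root_hydraulics$K_x,
                         L_r = cfg$root_hydraulics$L_r,
                         radius = cfg$root_hydraulics$radius,
                         h_collar_min = cfg$water$h_collar_min %||% -Inf)
    sink <- assemble_sink(segs, grid, xylem$J_r)
  }

  episodes <- do.call(rbind, c(
    lapply(seq_along(w$cs), function(r) {
      ep <- w$cs[[r]]$episodes
      if (w$cs[[r]]$phase == "recovery")
        ep <- rbind(ep, data.frame(t0 = w$cs[[r]]$t0, t1 = w$cs[[r]]$t1,
                                   t2 = w$cs[[r]]$t2))
      if (nrow(ep) > 0) cbind(root = r, ep) else NULL
    }),
    list(data.frame(root = integer(0), t0 = numeric(0), t1 = numeric(0),
                    t2 = numeric(0)))))

  sim <- structure(list(
    config = cfg, traits = tr, grid = grid, obstacles = obstacles,
    roots = w$roots, segments = seg_table(), tips = w$tip,
    snapshots = snapshots,
    tip_log = if (length(tip_log)) do.call(rbind, tip_log)
    else data.frame(),
    collar = if (length(collar_log)) do.call(rbind, collar_log)
    else data.frame(),
    episodes = episodes, branch_points = w$queue,
    water = wstate, sink = sink, xylem = xylem,
    seed = cfg$seed), class = "rsa_simulation")

  if (!is.null(cfg$out_dir)) write_run_outputs(sim, cfg$out_dir)
  sim
}

# advance a single root tip over [ts, te]
advance_one_tip <- function(w, rid, ts, te, grid, wstate, R_e, gr_e,
                            obstacles, tr, g_vec, add_segment) {
  dt_eff <- w$tip$dt_pending[rid]
  w$tip$dt_pending[rid] <- te - ts
  if (dt_eff <= 1e-12) return(invisible())
  pos <- c(w$tip$x[rid], w$tip$z[rid])
  d_old <- c(w$tip$dx[rid], w$tip$dz[rid])
  order <- w$roots$order[rid]
  birth <- w$roots$birth[rid]

  phase <- "free"
  near <- NULL
  if (length(obstacles) > 0) {
    near <- distance_to_obstacle(pos[1], pos[2], obstacles)
    in_contact <- near$distance <= tr$contact_threshold
    w$cs[[rid]] <- update_contact_state(w$cs[[rid]], in_contact, ts, d_old)
    phase <- w$cs[[rid]]$phase
  }

  # elongation rate at the tip
  age <- max(0, ts - birth)
  E_max <- e_max_at(tr, order, age)
  elem <- locate_element(grid, pos[1], pos[2])
  psi <- head_to_potential(interp_nodal(grid, wstate$h, pos[1], pos[2]))
  E <- elongation_rate(E_max, R_e[elem], psi)
  step_len <- E * dt_eff

  # penetration-resistance gradient term
  gvec <- c(interp_elem(grid, gr_e[, 1], pos[1], pos[2]),
            interp_elem(grid, gr_e[, 2], pos[1], pos[2]))
  if (sqrt(sum(gvec^2)) < tr$grad_tol) gvec <- c(0, 0)

  if (phase == "contact") {
    d <- growth_direction(d_old, g_vec, gvec, W_g = 1, W_r = tr$W_r,
                          delta_sample = 0, grad_tol = tr$grad_tol)
    if (step_len > 0)
      d <- contact_direction_policy(pos, obstacles[[near$obstacle]], d,
                                    step_len, g_vec)
  } else if (phase == "recovery") {
    cs <- w$cs[[rid]]
    hist <- if (cs$first_recovery_step) cs$dbar else d_old
    w$cs[[rid]]$first_recovery_step <- FALSE
    d <- growth_direction(d_old, g_vec, gvec, W_g = tr$W_g, W_r = tr$W_r,
                          w_hist = w_o_weight(cs, ts), hist = hist,
                          grad_tol = tr$grad_tol)
  } else {
    dev <- sample_deviation(tr$delta)
    d <- growth_direction(d_old, g_vec, gvec, W_g = tr$W_g, W_r = tr$W_r,
                          delta_sample = dev, grad_tol = tr$grad_tol)
  }

  if (step_len <= 1e-12) {
    w$tip$dx[rid] <- d[1]; w$tip$dz[rid] <- d[2]
    return(invisible())
  }

  target <- pos + step_len * d
  target <- clip_step_at_obstacles(pos, target, obstacles)
  cl <- clip_to_domain(pos, target, grid)
  target <- cl$p
  if (cl$hit) w$tip$halted[rid] <- TRUE
  alen <- sqrt(sum((target - pos)^2))
  # steps clipped to (near) nothing update the direction only; a segment
  # this short would make the xylem system numerically singular
  if (alen > 1e-6) {
    d_exec <- (target - pos) / alen
    parent_seg <- w$last_seg[rid]
    sid <- add_segment(rid, parent_seg, pos, target, te, order)
    w$last_seg[rid] <- sid

    # branch-point emission by arc length
    if (order < tr$max_order) {
      arc0 <- w$tip$arc[rid]
      sp <- tr$spacing
      k <- floor(arc0 / sp + 1e-9) + 1
      while (k * sp <= arc0 + alen + 1e-12) {
        if (k * sp > arc0 + 1e-9) {
          frac <- min(1, max(0, (k * sp - arc0) / alen))
          bp <- pos + frac * (target - pos)
          t_pass <- (te - dt_eff) + frac * dt_eff
          nb <- w$roots$n_bp[rid]
          side <- if (nb %% 2L == 0L) 1L else -1L
          first <- nb == 0L
          t_act <- if (first && tr$first_lateral_from_birth)
            max(t_pass, birth + tr$tip_delay)
          else t_pass + tr$tip_delay
          w$roots$n_bp[rid] <- nb + 1L
          w$queue[nrow(w$queue) + 1L, ] <-
            list(rid, k * sp, bp[1], bp[2], d_exec[1], d_exec[2],
                 side, sid, t_pass, t_act, order + 1L, FALSE)
        }
        k <- k + 1
      }
    }
    w$tip$x[rid] <- target[1]; w$tip$z[rid] <- target[2]
    w$tip$arc[rid] <- arc0_safe(w$tip$arc[rid]) + alen
    w$tip$dx[rid] <- d_exec[1]; w$tip$dz[rid] <- d_exec[2]
  } else {
    w$tip$dx[rid] <- d[1]; w$tip$dz[rid] <- d[2]
  }
  invisible()
}

arc0_safe <- function(a) if (is.na(a)) 0 else a

#' @export
print.rsa_simulation <- function(x, ...) {
  cat(sprintf(
    "rsa_simulation: %d roots (%d axes), %d segments, total length %.3g cm\n",
    nrow(x$roots), sum(x$roots$order == 1), nrow(x$segments),
    sum(x$segments$len)))
  cat(sprintf("  horizon %g day, seed %s\n", x$config$time$t_end,
              format(x$seed)))
  invisible(x)
}

# write RSML / CSV / VTK artifacts for a finished run
write_run_outputs <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_rsml(sim, file.path(out_dir, "root_system.rsml"))
  utils::write.csv(sim$segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$tip_log, file.path(out_dir, "tip_log.csv"),
                   row.names = FALSE)
  write_vtk_fields(sim$grid, sim$water, sim$sink,
                   file.path(out_dir, "fields.vtk"))
  invisible(out_dir)
}
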