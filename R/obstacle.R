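#' Rigid rectangular obstacle
#'
#' An obstacle is a rotated rectangle in the growth plane, modelled as a
#' region of very stiff, quasi-impermeable substrate (high bulk density,
#' low saturated conductivity) rather than as a hole in the mesh.
#'
#' @param center numeric length-2, rectangle centre (cm).
#' @param length long-edge length (cm), default 2.
#' @param width short-edge width (cm), default 0.2.
#' @param eta inclination of the long edge to the horizontal (degrees).
#' @param rho_b bulk density of the obstacle material (g/cm^3).
#' @param K_s saturated conductivity of the obstacle material (cm/day).
#' @return An object of class `obstacle` with cached corner coordinates.
#' @export
obstacle <- function(center, length = 2, width = 0.2, eta = 0,
                     rho_b = 1.4, K_s = 5) {
  stopifnot(base::length(center) == 2, length > 0, width > 0)
  th <- eta * pi / 180
  u <- c(cos(th), sin(th))          # along the long edge
  v <- c(-sin(th), cos(th))         # normal
  hl <- length / 2
  hw <- width / 2
  corners <- rbind(center + hl * u + hw * v,
                   center - hl * u + hw * v,
                   center - hl * u - hw * v,
                   center + hl * u - hw * v)
  structure(list(center = center, length = length, width = width,
                 eta = eta, u = u, v = v, corners = corners,
                 rho_b = rho_b, K_s = K_s),
            class = "obstacle")
}

#' @export
print.obstacle <- function(x, ...) {
  cat(sprintf("obstacle: %g x %g cm at (%g, %g), eta=%g deg\n",
              x$length, x$width, x$center[1], x$center[2], x$eta))
  invisible(x)
}

# local coordinates (along, across) of points relative to the rectangle
obstacle_local <- function(obs, x, z) {
  dx <- x - obs$center[1]
  dz <- z - obs$center[2]
  cbind(a = dx * obs$u[1] + dz * obs$u[2],
        b = dx * obs$v[1] + dz * obs$v[2])
}

#' Point-in-obstacle test
#'
#' @param obs an [obstacle()].
#' @param x,z coordinates (cm); vectorised.
#' @param strict if `TRUE`, boundary points do not count as inside.
#' @return Logical vector.
#' @export
point_in_obstacle <- function(obs, x, z, strict = FALSE) {
  lc <- obstacle_local(obs, x, z)
  hl <- obs$length / 2
  hw <- obs$width / 2
  if (strict) abs(lc[, "a"]) < hl - 1e-12 & abs(lc[, "b"]) < hw - 1e-12
  else abs(lc[, "a"]) <= hl + 1e-12 & abs(lc[, "b"]) <= hw + 1e-12
}

#' Assign obstacle materials to grid elements
#'
#' Every element whose centroid lies inside an obstacle rectangle gets
#' that obstacle's material index (`1 + position in the obstacle list`);
#' all other elements keep the substrate material 1. Later obstacles
#' override earlier ones where rectangles overlap.
#'
#' @param obstacles list of [obstacle()] objects (possibly empty).
#' @param grid a [soil_grid()].
#' @return Integer vector of length `grid$nelem`.
#' @export
rasterize_obstacles <- function(obstacles, grid) {
  elem_mat <- rep(1L, grid$nelem)
  for (k in seq_along(obstacles)) {
    obs <- obstacles[[k]]
    if (any(obs$corners[, 1] < -1e-9 | obs$corners[, 1] > grid$width + 1e-9 |
            obs$corners[, 2] < -1e-9 | obs$corners[, 2] > grid$height + 1e-9))
      stop("obstacle ", k, " extends outside the grid domain")
    inside <- point_in_obstacle(obs, grid$elem_x, grid$elem_z)
    elem_mat[inside] <- k + 1L
  }
  elem_mat
}

#' Build the material list for a substrate plus obstacles
#'
#' Obstacle materials inherit the substrate's retention shape and differ
#' in bulk density and saturated conductivity.
#'
#' @param substrate a [van_genuchten()] soil.
#' @param obstacles list of [obstacle()] objects.
#' @return List of materials aligned with [rasterize_obstacles()] codes.
#' @export
obstacle_materials <- function(substrate, obstacles) {
  mats <- list(substrate)
  for (obs in obstacles) {
    m <- substrate
    m$rho_b <- obs$rho_b
    m$K_s <- obs$K_s
    mats <- c(mats, list(m))
  }
  mats
}

#' Distance from a point to the nearest obstacle boundary
#'
#' @param x,z tip coordinates (cm).
#' @param obstacles list of [obstacle()] objects.
#' @return A list with `distance` (cm, Euclidean distance to the nearest
#'   obstacle periphery; `Inf` when no obstacles), `obstacle` (index of
#'   the nearest obstacle or `NA`), `tangent` (unit tangent of the
#'   nearest edge, sense unresolved), and `inside` (logical).
#' @export
distance_to_obstacle <- function(x, z, obstacles) {
  best <- list(distance = Inf, obstacle = NA_integer_,
               tangent = c(NA_real_, NA_real_), inside = FALSE)
  for (k in seq_along(obstacles)) {
    obs <- obstacles[[k]]
    lc <- obstacle_local(obs, x, z)
    a <- lc[1, "a"]; b <- lc[1, "b"]
    hl <- obs$length / 2
    hw <- obs$width / 2
    da <- abs(a) - hl
    db <- abs(b) - hw
    if (da <= 0 && db <= 0) {
      # inside (or on boundary): distance to nearest edge
      d <- min(-da, -db)
      tang <- if (-da < -db) obs$v else obs$u   # nearest edge is a short end
      inside <- TRUE
    } else {
      ca <- max(da, 0)
      cb <- max(db, 0)
      d <- sqrt(ca^2 + cb^2)
      # nearest edge: long edge when the along-axis excess dominates is
      # the short end; otherwise the long side
      tang <- if (ca > 0 && cb == 0) obs$v
      else if (cb > 0 && ca == 0) obs$u
      else if (ca >= cb) obs$v else obs$u
      inside <- FALSE
    }
    if (d < best$distance) {
      best <- list(distance = d, obstacle = k, tangent = tang,
                   inside = inside)
    }
  }
  best
}

#' Fresh obstacle-contact state for a root tip
#'
#' The per-tip phase machine starts in phase `free`. `W_oi` is the
#' initial history weight at the start of recovery and `kappa` the
#' recovery/contact duration proportionality.
#'
#' @param W_oi initial recovery weight (> 1), default 5.
#' @param kappa recovery-time proportionality (-), default 2.
#' @return A list of class `contact_state`.
#' @export
new_contact_state <- function(W_oi = 5, kappa = 2) {
  if (W_oi <= 1) stop("W_oi must exceed 1")
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(phase = "free", t0 = NA_real_, t1 = NA_real_,
                 t2 = NA_real_, W_oi = W_oi, kappa = kappa,
                 dbar = c(0, 0), n_dir = 0L, last_t = -Inf,
                 first_recovery_step = FALSE,
                 episodes = data.frame(t0 = numeric(0), t1 = numeric(0),
                                       t2 = numeric(0))),
            class = "contact_state")
}

#' Advance the contact/recovery phase machine
#'
#' Transitions: `free -> contact` at first contact (records `t0`, starts
#' accumulating the mean contact direction); `contact -> recovery` at
#' loss of contact (records `t1`, freezes the mean direction, sets
#' `t2 = t1 + kappa * (t1 - t0)`); `recovery -> free` once `t >= t2`.
#' Any new contact during recovery cancels it and restarts at `contact`
#' with a fresh `t0`. Completed episodes accumulate in
#' `state$episodes`.
#'
#' @param state a [new_contact_state()].
#' @param in_contact logical, whether the tip currently touches an
#'   obstacle (distance below threshold).
#' @param t current time (day); must not regress between calls.
#' @param direction unit direction of the previous growth step, folded
#'   into the running mean while in contact (may be `NULL` before any
#'   step).
#' @return The updated state.
#' @export
update_contact_state <- function(state, in_contact, t, direction = NULL) {
  if (t < state$last_t - 1e-12) stop("time regression in contact state")
  state$last_t <- t
  if (state$phase == "contact" && !is.null(direction)) {
    state$dbar <- state$dbar + direction / sqrt(sum(direction^2))
    state$n_dir <- state$n_dir + 1L
  }
  if (in_contact) {
    if (state$phase != "contact") {
      # entering (or re-entering, cancelling recovery)
      state$phase <- "contact"
      state$t0 <- t
      state$t1 <- NA_real_
      state$t2 <- NA_real_
      state$dbar <- c(0, 0)
      state$n_dir <- 0L
    }
  } else {
    if (state$phase == "contact") {
      state$phase <- "recovery"
      state$t1 <- t
      state$t2 <- t + state$kappa * (t - state$t0)
      if (state$n_dir > 0L)
        state$dbar <- state$dbar / sqrt(sum(state$dbar^2))
      else if (!is.null(direction))
        state$dbar <- direction / sqrt(sum(direction^2))
      state$first_recovery_step <- TRUE
      if (state$t2 <= state$t1 + 1e-12) {
        # zero-length contact: nothing to recover from
        state$phase <- "free"
      }
    }
    if (state$phase == "recovery" && t >= state$t2 - 1e-12) {
      state$episodes <- rbind(state$episodes,
                              data.frame(t0 = state$t0, t1 = state$t1,
                                         t2 = state$t2))
      state$phase <- "free"
    }
  }
  state
}

#' History weight W_o of the obstacle model
#'
#' Equals 1 while the tip is in contact; during recovery it drops
#' linearly from `W_oi` at `t1` to 0 at `t2`; zero in phase `free` or
#' once `t >= t2`.
#'
#' @param state a [new_contact_state()].
#' @param t evaluation time (day).
#' @return Scalar weight.
#' @export
w_o_weight <- function(state, t) {
  if (state$phase == "contact") {
    if (t < state$t0 - 1e-12) stop("t precedes contact start t0")
    return(1)
  }
  if (state$phase == "recovery") {
    if (t < state$t0 - 1e-12) stop("t precedes contact start t0")
    if (t >= state$t2) return(0)
    if (t < state$t1) return(1)
    return(state$W_oi * (1 - (t - state$t1) / (state$t2 - state$t1)))
  }
  0
}

#' Effective growth direction while sliding on an obstacle
#'
#' During contact the geotropism weight is forced to 1 and the random
#' deviation is suppressed; if the candidate step would enter the
#' obstacle rectangle, the direction is projected onto the nearest edge
#' tangent with the sense that preserves forward motion (falling back to
#' the tangent sense of the gravity component for a perfectly normal
#' approach).
#'
#' @param pos tip position, numeric length-2 (cm).
#' @param obs the [obstacle()] in contact.
#' @param dir candidate unit growth direction (after weighting).
#' @param step_len length of the impending step (cm), used to test
#'   whether the step would penetrate the obstacle.
#' @param g unit gravity vector, default `c(0, -1)`.
#' @return Unit direction actually used for the step.
#' @export
contact_direction_policy <- function(pos, obs, dir, step_len,
                                     g = c(0, -1)) {
  target <- pos + step_len * dir
  enters <- point_in_obstacle(obs, target[1], target[2], strict = TRUE) ||
    segment_enters_obstacle(obs, pos, target)
  if (!enters) return(dir)
  near <- distance_to_obstacle(pos[1], pos[2], list(obs))
  tang <- near$tangent
  proj <- sum(dir * tang)
  if (abs(proj) > 1e-9) {
    d <- sign(proj) * tang
  } else {
    gproj <- sum(g * tang)
    if (abs(gproj) < 1e-9)
      stop("degenerate contact: direction and gravity both normal to edge")
    d <- sign(gproj) * tang
  }
  d / sqrt(sum(d^2))
}

# does the open segment p0 -> p1 pass through the rectangle interior?
segment_enters_obstacle <- function(obs, p0, p1) {
  mid <- (p0 + p1) / 2
  any(point_in_obstacle(obs, c(mid[1], p1[1]), c(mid[2], p1[2]),
                        strict = TRUE))
}

# clip a step p0 -> p1 so its endpoint does not lie strictly inside any
# obstacle; returns the clipped endpoint (bisection on the entry point)
clip_step_at_obstacles <- function(p0, p1, obstacles) {
  for (obs in obstacles) {
    if (point_in_obstacle(obs, p1[1], p1[2], strict = TRUE)) {
      lo <- 0; hi <- 1
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        pm <- p0 + mid * (p1 - p0)
        if (point_in_obstacle(obs, pm[1], pm[2], strict = TRUE)) hi <- mid
        else lo <- mid
      }
      p1 <- p0 + lo * (p1 - p0)
    }
  }
  p1
}
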