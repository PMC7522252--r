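#' Specification of a synthetic trait/trajectory fixture
#'
#' The fixture generator emulates the statistical structure of the
#' wheat tracing data set: decreasing axis elongation with age,
#' constant lateral elongation, a five-axis emergence schedule, a
#' growth-angle trajectory around an inclined obstacle with a plateau at
#' the inclination followed by a recovery governed by `kappa` and
#' `W_oi`, and network-index time series. Gaussian noise of configurable
#' standard deviation can be superposed on every output.
#'
#' @param seed RNG seed.
#' @param noise_sd named list of noise standard deviations:
#'   `elongation` (cm/day), `beta` (deg), `index` (relative).
#' @param eta obstacle inclinations (degrees) for beta fixtures.
#' @param t0,t1 contact start / end times (day) of the beta fixtures.
#' @param kappa,W_oi obstacle-model parameters of the beta fixtures.
#' @param W_g geotropism weight driving the recovery shape.
#' @param dt sampling step (day).
#' @param t_end fixture horizon (day).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         noise_sd = list(elongation = 0, beta = 0,
                                         index = 0),
                         eta = c(0, 30, 45), t0 = 1, t1 = 2,
                         kappa = 2, W_oi = 5, W_g = 0.1,
                         dt = 0.05, t_end = 6) {
  sd_def <- list(elongation = 0, beta = 0, index = 0)
  noise_sd <- utils::modifyList(sd_def, noise_sd)
  if (any(unlist(noise_sd) < 0)) stop("noise SDs must be >= 0")
  structure(list(seed = seed, noise_sd = noise_sd, eta = eta,
                 t0 = t0, t1 = t1, kappa = kappa, W_oi = W_oi,
                 W_g = W_g, dt = dt, t_end = t_end),
            class = "fixture_spec")
}

#' Deterministic growth-angle trajectory around an obstacle
#'
#' Iterates the weighted direction-update rule itself (history weight
#' `W_o(t)` against gravity weight `W_g`, no resistance term, no random
#' deviation): beta stays at 90 deg before contact, drops to the
#' obstacle inclination during contact, then recovers as `W_o` decays
#' linearly from `W_oi` to 0 over `kappa * (t1 - t0)` and gravity takes
#' over.
#'
#' @param eta obstacle inclination (degrees).
#' @param t0,t1 contact start / end (day).
#' @param kappa,W_oi,W_g obstacle-model parameters.
#' @param dt time step (day).
#' @param t_end horizon (day).
#' @return Data frame `time`, `beta` (deg), `phase`.
#' @export
fixture_beta_trajectory <- function(eta, t0, t1, kappa, W_oi, W_g = 0.1,
                                    dt = 0.05, t_end = NULL) {
  t2 <- t1 + kappa * (t1 - t0)
  if (is.null(t_end)) t_end <- t2 + (t2 - t1)
  times <- seq(dt, t_end, by = dt)
  g <- c(0, -1)
  th <- eta * pi / 180
  d_slide <- c(-cos(th), -sin(th))     # sliding down the incline
  d <- c(0, -1)
  beta <- numeric(length(times))
  phase <- character(length(times))
  first_rec <- TRUE
  for (i in seq_along(times)) {
    tt <- times[i]
    if (tt < t0) {
      phase[i] <- "free"
    } else if (tt <= t1) {
      d <- d_slide
      phase[i] <- "contact"
    } else if (tt < t2) {
      phase[i] <- "recovery"
      w_o <- W_oi * (1 - (tt - t1) / (t2 - t1))
      hist <- if (first_rec) d_slide else d
      first_rec <- FALSE
      v <- w_o * hist + W_g * g
      d <- v / sqrt(sum(v^2))
    } else {
      phase[i] <- "free"
      v <- d + W_g * g
      d <- v / sqrt(sum(v^2))
    }
    beta[i] <- beta_angle(d[1], d[2])
  }
  data.frame(time = times, beta = beta, phase = phase)
}

#' Parametric network-index series family
#'
#' Smooth synthetic family of index time series used as a surrogate
#' simulator in calibration tests: total length is the two-stage sum of
#' axis growth plus lateral growth starting after the tip delay;
#' foraging area and branching density depend monotonically on the
#' direction weights, emulating lateral spread.
#'
#' @param params named list/row with `tip_delay`, `W_g`, `W_r`, `delta`.
#' @param times evaluation times (day).
#' @return Data frame `time`, `total_length`, `foraging_area`,
#'   `branching_density`.
#' @export
fixture_index_series <- function(params, times) {
  td <- as.numeric(params$tip_delay)
  wg <- as.numeric(params$W_g)
  wr <- as.numeric(params$W_r)
  de <- as.numeric(params$delta)
  axes <- 5 * pmin(times, 3.5) * (2.0 - 0.2 * pmin(times, 3.5))
  lat_t <- pmax(times - td, 0)
  laterals <- 0.4 * (1 / 0.3) * lat_t^2
  tl <- axes + laterals
  spread <- (1 + de / 35) * (1 + 0.5 * wr) / (1 + 2 * wg)
  fa <- 2.0 * spread * pmin(times, 4)^1.5
  bd <- (1 / 0.3) * (1 - exp(-2 * lat_t)) * (1 - 0.2 * wg)
  data.frame(time = times, total_length = tl, foraging_area = fa,
             branching_density = bd)
}

#' Generate a synthetic fixture data set
#'
#' Seeded and reproducible. With zero noise all outputs lie exactly on
#' the generating curves; beta fixtures satisfy the plateau-at-eta /
#' linear-recovery structure with the configured `kappa`, and the
#' episode table reproduces `kappa` exactly under [estimate_kappa()].
#'
#' @param spec a [fixture_spec()].
#' @return List with `axis_elongation` (age, rate), `lateral_elongation`,
#'   `beta` (named list per eta of data frames), `episodes`
#'   (t0, t1, t2), and `indices` (index time series at the reference
#'   parameters).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  ns <- spec$noise_sd
  ages <- seq(0, 3.5, by = 0.5)
  axis_rate <- pmax(2.0 - 0.45 * ages, 0.2) +
    stats::rnorm(length(ages), 0, ns$elongation)
  lat_ages <- seq(0, 2, by = 0.5)
  lat_rate <- rep(0.4, length(lat_ages)) +
    stats::rnorm(length(lat_ages), 0, ns$elongation)
  beta <- lapply(spec$eta, function(e) {
    b <- fixture_beta_trajectory(e, spec$t0, spec$t1, spec$kappa,
                                 spec$W_oi, spec$W_g, spec$dt,
                                 spec$t_end)
    b$beta <- b$beta + stats::rnorm(nrow(b), 0, ns$beta)
    b
  })
  names(beta) <- as.character(spec$eta)
  contacts <- data.frame(t0 = c(spec$t0, 0.5, 1.5),
                         t1 = c(spec$t1, 1.4, 2.1))
  episodes <- data.frame(t0 = contacts$t0, t1 = contacts$t1,
                         t2 = contacts$t1 +
                           spec$kappa * (contacts$t1 - contacts$t0))
  times <- seq(0.5, spec$t_end, by = 0.5)
  idx <- fixture_index_series(list(tip_delay = 2.1, W_g = spec$W_g,
                                   W_r = 0.45, delta = 35), times)
  for (nm in c("total_length", "foraging_area", "branching_density"))
    idx[[nm]] <- idx[[nm]] * (1 + stats::rnorm(nrow(idx), 0, ns$index))
  list(axis_elongation = data.frame(age = ages, rate = pmax(axis_rate, 0)),
       lateral_elongation = data.frame(age = lat_ages,
                                       rate = pmax(lat_rate, 0)),
       beta = beta, episodes = episodes, indices = idx)
}
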