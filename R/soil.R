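#' Van Genuchten substrate description
#'
#' Bundles the Van Genuchten-Mualem retention/conductivity parameters of a
#' substrate material together with its bulk density. The shape parameter
#' `m` is always derived as `1 - 1/n`.
#'
#' @param theta_r residual volumetric water content (-).
#' @param theta_s saturated volumetric water content (-).
#' @param alpha retention shape parameter (1/cm).
#' @param n retention shape parameter (-), must exceed 1.
#' @param K_s saturated hydraulic conductivity (cm/day).
#' @param l_pore Mualem pore-connectivity exponent (-). Defaults to the
#'   standard Mualem value 0.5.
#' @param rho_b dry bulk density (g/cm^3), used by the penetration
#'   resistance model.
#'
#' @return An object of class `vg_soil`.
#' @export
#' @examples
#' van_genuchten()          # calibration substrate defaults
van_genuchten <- function(theta_r = 0.06, theta_s = 0.41, alpha = 0.03,
                          n = 2.51, K_s = 10.24, l_pore = 0.5,
                          rho_b = 1.2) {
  stopifnot(is.numeric(theta_r), is.numeric(theta_s), is.numeric(alpha),
            is.numeric(n), is.numeric(K_s))
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    stop("require 0 <= theta_r < theta_s <= 1")
  if (n <= 1) stop("Van Genuchten n must be > 1")
  if (alpha <= 0) stop("alpha must be > 0")
  if (K_s <= 0) stop("K_s must be > 0")
  if (rho_b <= 0) stop("rho_b must be > 0")
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n = n, m = 1 - 1 / n, K_s = K_s, l_pore = l_pore,
                 rho_b = rho_b),
            class = "vg_soil")
}

#' @export
print.vg_soil <- function(x, ...) {
  cat(sprintf(
    "Van Genuchten substrate: theta_r=%g theta_s=%g alpha=%g 1/cm n=%g (m=%g)\n",
    x$theta_r, x$theta_s, x$alpha, x$n, x$m))
  cat(sprintf("  K_s=%g cm/day  l=%g  rho_b=%g g/cm^3\n",
              x$K_s, x$l_pore, x$rho_b))
  invisible(x)
}

#' Effective saturation from water content
#'
#' `Se = (theta - theta_r) / (theta_s - theta_r)`.
#'
#' @param theta volumetric water content (-), must lie in
#'   `[theta_r, theta_s]`.
#' @param soil a [van_genuchten()] object.
#' @return Effective saturation in `[0, 1]`.
#' @export
effective_saturation <- function(theta, soil) {
  tol <- 1e-12
  if (any(theta < soil$theta_r - tol | theta > soil$theta_s + tol))
    stop("theta outside [theta_r, theta_s]")
  pmin(1, pmax(0, (theta - soil$theta_r) / (soil$theta_s - soil$theta_r)))
}

#' Water retention curve theta(h)
#'
#' Van Genuchten retention: saturated content for non-negative heads,
#' `theta_r + (theta_s - theta_r) / (1 + (alpha*|h|)^n)^m` otherwise.
#'
#' @param h pressure head (cm), negative when unsaturated. Vectorised.
#' @param soil a [van_genuchten()] object.
#' @return Volumetric water content (-).
#' @export
theta_of_h <- function(h, soil) {
  wet <- h >= 0
  ah <- soil$alpha * abs(h)
  th <- soil$theta_r +
    (soil$theta_s - soil$theta_r) * (1 + ah^soil$n)^(-soil$m)
  th[wet] <- soil$theta_s
  th
}

#' Specific moisture capacity d(theta)/dh
#'
#' Analytic derivative of [theta_of_h()]; zero at and above saturation.
#'
#' @inheritParams theta_of_h
#' @return Capacity (1/cm).
#' @export
capacity_of_h <- function(h, soil) {
  wet <- h >= 0
  ah <- soil$alpha * abs(h)
  num <- soil$m * soil$n * soil$alpha * ah^(soil$n - 1)
  cap <- (soil$theta_s - soil$theta_r) * num * (1 + ah^soil$n)^(-soil$m - 1)
  cap[wet] <- 0
  cap
}

#' Unsaturated hydraulic conductivity K(h)
#'
#' Mualem-Van Genuchten closed form
#' `K = K_s * Se^l * (1 - (1 - Se^(1/m))^m)^2` with
#' `Se = (1 + (alpha*|h|)^n)^(-m)`; equals `K_s` at and above saturation.
#'
#' @inheritParams theta_of_h
#' @return Conductivity (cm/day), in `(0, K_s]`.
#' @export
k_of_h <- function(h, soil) {
  wet <- h >= 0
  ah <- soil$alpha * abs(h)
  se <- (1 + ah^soil$n)^(-soil$m)
  k <- soil$K_s * se^soil$l_pore *
    (1 - (1 - se^(1 / soil$m))^soil$m)^2
  k[wet] <- soil$K_s
  # dry-limit floor: keeps the flow matrix non-singular when the
  # substrate dries to near-residual content
  pmax(k, soil$K_s * 1e-12)
}

#' Substrate penetration resistance
#'
#' Empirical pedotransfer relation
#' `R = exp(0.35 * log10(|psi| * Se) + 0.93 * rho_b + 1.26)` (kPa), with
#' the product `|psi|*Se` clamped below by `eps` so the resistance stays
#' finite in saturated substrate.
#'
#' @param psi water potential (kPa); only its magnitude enters.
#' @param Se effective saturation degree in `[0, 1]`.
#' @param rho_b bulk density (g/cm^3).
#' @param eps lower clamp on `|psi|*Se` (kPa).
#' @return Penetration resistance (kPa), strictly positive. Vectorised.
#' @export
penetration_resistance <- function(psi, Se, rho_b, eps = 1e-6) {
  if (any(Se < -1e-12 | Se > 1 + 1e-12)) stop("Se outside [0, 1]")
  if (any(rho_b <= 0)) stop("rho_b must be > 0")
  x <- pmax(abs(psi) * pmin(pmax(Se, 0), 1), eps)
  exp(0.35 * log10(x) + 0.93 * rho_b + 1.26)
}

#' Root elongation rate under penetration resistance
#'
#' `E = E_max * (1 - R_ave / (4000 + 2.33 * |psi|))`, clamped to
#' `[0, E_max]`. The denominator terms are in kPa.
#'
#' @param E_max maximum (genetic) elongation rate (cm/day).
#' @param R_ave average penetration resistance at the tip (kPa).
#' @param psi water potential at the tip (kPa).
#' @return Elongation rate (cm/day). Vectorised.
#' @export
elongation_rate <- function(E_max, R_ave, psi) {
  if (any(E_max < 0)) stop("E_max must be >= 0")
  e <- E_max * (1 - R_ave / (4000 + 2.33 * abs(psi)))
  pmin(pmax(e, 0), E_max)
}

#' Convert pressure head to water potential
#'
#' One centimetre of water column corresponds to 0.09806 kPa.
#'
#' @param h pressure head (cm).
#' @return Water potential (kPa), negative for negative heads.
#' @export
head_to_potential <- function(h) -0.09806 * (-h)
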