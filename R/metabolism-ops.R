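#' Glucose transporter count under hypoxic compensation
#'
#' Transporter (GLUT) surface count
#' \eqn{N_G = N_0 (\alpha_r - 2) / (\alpha_r - (\alpha_r - 2) h)}. The
#' compensation is constructed so that, for fixed surface glucose, energy
#' production per MCS is independent of the metabolic mode h: fermenting
#' cells upregulate transporters exactly enough to offset the lower ATP
#' yield, so there is no intrinsic selection bias toward either mode.
#'
#' @param n0 Intrinsic growth signal (capped at
#'   \code{metabolic_params()$n0_cap}).
#' @param h Hypoxia fraction in [0, 1].
#' @param params A \code{\link{metabolic_params}}.
#' @return Transporter count (vectorized).
#' @examples
#' glut_count(250, 0) # 250 * 36/38
#' glut_count(250, 1) # 250 * 36/2 = 4500
#' @export
glut_count <- function(n0, h, params = metabolic_params()) {
  a <- params$alpha_r
  if (any(h < 0 | h > 1)) stop("glut_count(): h must lie in [0,1]")
  n0 <- pmin(n0, params$n0_cap)
  den <- a - (a - 2) * h
  if (any(den <= 0)) stop("glut_count(): degenerate denominator") # unreachable for a > 2
  n0 * (a - 2) / den
}

#' Hypoxia factor update (HIF switch)
#'
#' \eqn{h' = 1 - [O_2^n / (\kappa_h^n + O_2^n)]\,[1 - \zeta^n /
#' (\kappa_\zeta^n + \zeta^n)]}: hypoxia is relieved by oxygen and
#' re-imposed by accumulated reactive oxygen species (ROS), which stabilizes
#' the hypoxic, fermentative state even after oxygen returns (the metabolic
#' lock-in). Evaluated on the previous step's oxygen and ROS (one-MCS
#' signaling delay).
#'
#' @param mean_o2 Mean oxygen concentration over the cell's sites.
#' @param zeta ROS level (>= 0).
#' @param kappa_h,kappa_z Hill thresholds (phenotype parameters).
#' @param n_h,n_z Hill exponents.
#' @return Updated hypoxia fraction in [0, 1] (vectorized).
#' @examples
#' update_hypoxia(0, 0, 0.1, 0.5)      # 1
#' update_hypoxia(0.1, 0.5, 0.1, 0.5)  # 0.75 at the double midpoint
#' @export
update_hypoxia <- function(mean_o2, zeta, kappa_h, kappa_z,
                           n_h = metabolic_params()$n_h,
                           n_z = metabolic_params()$n_z) {
  stopifnot(all(mean_o2 >= 0), all(zeta >= 0))
  o2_term <- mean_o2^n_h / (kappa_h^n_h + mean_o2^n_h)
  z_term <- zeta^n_z / (kappa_z^n_z + zeta^n_z)
  pmin(pmax(1 - o2_term * (1 - z_term), 0), 1)
}

#' ROS update
#'
#' \eqn{\zeta' = (1 - \omega_\zeta)\zeta + (1-h) U_g}: existing ROS decays
#' exponentially and respiration adds ROS in proportion to the glucose it
#' processes. (The printed update lacks the persistence factor and can go
#' negative; this amended form is used throughout, clamped at 0.)
#'
#' @param zeta Current ROS level (>= 0).
#' @param h Hypoxia fraction used in the producing step.
#' @param u_g Glucose taken up during the step (the respired share is
#'   \code{(1-h) * u_g}).
#' @param omega_z Decay constant per MCS.
#' @return Updated ROS level (>= 0, vectorized).
#' @examples
#' update_ros(1, 1, 5)   # 0.9: pure fermentation only decays ROS
#' update_ros(0, 0, 1)   # 1
#' @export
update_ros <- function(zeta, h, u_g, omega_z = metabolic_params()$omega_z) {
  stopifnot(all(zeta >= 0), all(u_g >= 0))
  pmax((1 - omega_z) * zeta + (1 - h) * u_g, 0)
}
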