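#' Target-volume (biomass) update from net energy
#'
#' With net energy \eqn{net = E_{prod} - E_m}: if net >= 0,
#' \eqn{dV^T = \alpha\,net - \beta (V^T - V)|V^T - V| -
#' \gamma\,\Theta(\zeta - \theta_R)}; the pressure term relaxes the target
#' volume toward the actual volume so a compressed cell grows more slowly
#' (orientation fixed against the printed formula, which would do the
#' opposite), and ROS above tolerance shrinks the cell at rate gamma. If
#' net < 0 the deficit is paid from biomass (catabolism):
#' \eqn{dV^T = \alpha\,net} and the energy is zeroed. A cell whose target
#' volume reaches zero has exhausted its mass and is dead.
#'
#' @param v,v_t Current and target volume (sites).
#' @param e_prod Energy produced this MCS.
#' @param zeta ROS level.
#' @param growth A \code{\link{growth_params}}.
#' @param e_m Basal metabolic cost per MCS.
#' @return List with \code{v_t} (updated target volume, floored at 0) and
#'   \code{dead} (logical: mass exhausted). Vectorized.
#' @examples
#' update_target_volume(25, 25, e_prod = 0.3, zeta = 0)$v_t # unchanged
#' @export
update_target_volume <- function(v, v_t, e_prod, zeta,
                                 growth = growth_params(),
                                 e_m = metabolic_params()$e_m) {
  net <- e_prod - e_m
  dv <- ifelse(net >= 0,
               growth$alpha * net -
                 growth$beta * (v_t - v) * abs(v_t - v) -
                 growth$gamma * (zeta > growth$theta_r),
               growth$alpha * net)
  new_vt <- v_t + dv
  list(v_t = pmax(new_vt, 0), dead = new_vt <= 0)
}

#' Division probability as a function of volume
#'
#' Sigmoid gate around the division volume with fuzzy width
#' \eqn{w = 0.05 V_D}: zero below \eqn{V_D - 3w}, one at or above
#' \eqn{V_D + 3w}, and
#' \eqn{(V - V_D)/(2\sqrt{w^2 + (V - V_D)^2}) + 1/2} between.
#'
#' @param v Current volume (sites).
#' @param v_d Division volume (phenotype parameter, > 0).
#' @param w_frac Window fraction (default 0.05).
#' @return Probability in [0, 1] (vectorized).
#' @examples
#' division_probability(50, 50) # 0.5
#' @export
division_probability <- function(v, v_d, w_frac = growth_params()$w_frac) {
  stopifnot(all(v_d > 0))
  w <- w_frac * v_d
  x <- v - v_d
  mid <- x / (2 * sqrt(w^2 + x^2)) + 0.5
  ifelse(v < v_d - 3 * w, 0, ifelse(v >= v_d + 3 * w, 1, mid))
}
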