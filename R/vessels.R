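#' Vessel blocking/unblocking schedule
#'
#' Vessels (immobilized endothelial cross-sections) switch between active
#' and blocked states once per MCS with a switching probability P; blocking
#' and unblocking use the same P, so the long-run active fraction is 1/2 for
#' every P and only the dosage pattern changes. Three laws for P are
#' supported: a constant, a geometric decrease in time
#' \eqn{P(t+1) = r P(t)} floored at \code{p_floor}, and a linear feedback on
#' tissue coverage \eqn{P(\rho) = 0.499 \rho + 0.001}.
#'
#' @param mode One of \code{"constant"}, \code{"geometric"},
#'   \code{"density_feedback"}.
#' @param p0 Initial switching probability (constant and geometric modes).
#' @param r Geometric ratio per MCS (geometric mode); published progressive
#'   tortuosity uses 0.999876 from P(0) = 0.5.
#' @param p_floor Floor below which the geometric law stops decreasing.
#' @param feedback_slope,feedback_intercept Coefficients of the
#'   density-feedback law.
#' @return List of class \code{vessel_schedule}.
#' @examples
#' blocking_probability(vessel_schedule("density_feedback"), coverage = 1)
#' @export
vessel_schedule <- function(mode = c("constant", "geometric",
                                     "density_feedback"),
                            p0 = 0.5, r = 0.999876, p_floor = 0.001,
                            feedback_slope = 0.499,
                            feedback_intercept = 0.001) {
  mode <- match.arg(mode)
  stopifnot(p0 >= 0, p0 <= 1, r > 0, r <= 1, p_floor >= 0)
  structure(list(mode = mode, p0 = p0, r = r, p_floor = p_floor,
                 feedback_slope = feedback_slope,
                 feedback_intercept = feedback_intercept),
            class = "vessel_schedule")
}

#' Switching probability prescribed by a schedule
#'
#' @param schedule A \code{\link{vessel_schedule}}.
#' @param t MCS clock (used by the geometric mode).
#' @param coverage Tissue coverage in [0, 1] (used by the density-feedback
#'   mode).
#' @return Switching probability (vectorized over \code{t}/\code{coverage}).
#' @examples
#' blocking_probability(vessel_schedule("geometric", p0 = 0.5), t = 1)
#' @export
blocking_probability <- function(schedule, t = 0, coverage = NA_real_) {
  switch(schedule$mode,
    constant = rep_len(schedule$p0, max(length(t), 1L)),
    geometric = pmax(schedule$p0 * schedule$r^t, schedule$p_floor),
    density_feedback = {
      if (any(is.na(coverage)) || any(coverage < 0) || any(coverage > 1)) {
        stop("blocking_probability(): density feedback needs coverage in [0,1]")
      }
      schedule$feedback_slope * coverage + schedule$feedback_intercept
    }
  )
}

#' Advance per-vessel active/blocked states by one MCS
#'
#' Each vessel independently flips its state with probability \code{p}.
#'
#' @param active Logical vector of per-vessel activity.
#' @param p Switching probability in [0, 1].
#' @return Updated logical vector.
#' @export
update_vessel_states <- function(active, p) {
  stopifnot(p >= 0, p <= 1)
  flip <- runif(length(active)) < p
  xor(active, flip)
}
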