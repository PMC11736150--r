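#' Weibull hazard parameters
#'
#' Each patient's 12-week predicted risks are converted to weekly event
#' probabilities via a Weibull cumulative hazard \eqn{H(t) = \lambda t^k}
#' with shape \eqn{k \ge 1}, so hazards are non-decreasing in time waited
#' (deterioration while waiting). The multipliers are the calibration knobs:
#' `mult_death` and `mult_hosp` scale the cumulative hazards, `mult_urgent`
#' scales the per-hospitalization urgent-conversion probability
#' (`min(1, mult_urgent * p_urgent_given_hosp)`).
#'
#' @param shape_death,shape_hosp Weibull shapes, >= 1 (1 = memoryless,
#'   constant weekly probability; default 1.5 encodes escalation).
#' @param mult_death,mult_hosp,mult_urgent Positive calibration multipliers
#'   (1 = use the predicted risks as-is).
#' @param risk_horizon Horizon (weeks) at which the predicted risks are
#'   defined; 12 for the triage-tool risks.
#' @return An object of class `hazard_params`.
#' @export
hazard_params <- function(shape_death = 1.5, shape_hosp = 1.5,
                          mult_death = 1, mult_hosp = 1, mult_urgent = 1,
                          risk_horizon = 12) {
  if (shape_death < 1 || shape_hosp < 1)
    stop("Weibull shapes must be >= 1 (non-decreasing hazards)",
         call. = FALSE)
  if (mult_death <= 0 || mult_hosp <= 0 || mult_urgent <= 0)
    stop("calibration multipliers must be positive", call. = FALSE)
  if (risk_horizon <= 0) stop("risk_horizon must be positive", call. = FALSE)
  structure(list(shape_death = shape_death, shape_hosp = shape_hosp,
                 mult_death = mult_death, mult_hosp = mult_hosp,
                 mult_urgent = mult_urgent, risk_horizon = risk_horizon),
            class = "hazard_params")
}

#' @export
print.hazard_params <- function(x, ...) {
  cat("Weibull hazard parameters\n")
  cat(sprintf("  shapes  : death %.3f, hosp %.3f (horizon %g weeks)\n",
              x$shape_death, x$shape_hosp, x$risk_horizon))
  cat(sprintf("  mults   : death %.4f, hosp %.4f, urgent %.4f\n",
              x$mult_death, x$mult_hosp, x$mult_urgent))
  invisible(x)
}

#' Weibull scale from a horizon risk
#'
#' Inverts the cumulative incidence at the risk horizon:
#' \eqn{\lambda = c \cdot (-\log(1 - p_{12})) / T^k}, so that with
#' multiplier \eqn{c = 1} the cumulative incidence at \eqn{T} reproduces the
#' predicted risk exactly.
#'
#' @param p12 Predicted risk(s) at the horizon, in `[0, 1)`.
#' @param shape Weibull shape `k`.
#' @param horizon Horizon `T` in weeks (default 12).
#' @param multiplier Calibration multiplier `c` (default 1).
#' @return Scale(s) `lambda` (vectorized over `p12`).
#' @export
weibull_scale_from_risk <- function(p12, shape, horizon = 12, multiplier = 1) {
  if (any(p12 < 0) || any(p12 >= 1))
    stop("horizon risk must lie in [0, 1); risk 1 implies an infinite hazard",
         call. = FALSE)
  multiplier * (-log1p(-p12)) / horizon^shape
}

#' Weekly event probability under a Weibull clock
#'
#' Probability of an event during week `t` (cycle `t`) conditional on no
#' event before: \eqn{q_t = 1 - \exp(-\lambda (t^k - (t-1)^k))}. Strictly
#' increasing in `t` for `k > 1`; constant for `k = 1`.
#'
#' @param lambda Weibull scale(s).
#' @param shape Weibull shape `k`.
#' @param t Week index, integer >= 1 (scalar or vector).
#' @return Weekly probability/ies.
#' @export
weekly_event_prob <- function(lambda, shape, t) {
  if (any(t < 1) || any(t != floor(t)))
    stop("'t' must be an integer week >= 1", call. = FALSE)
  -expm1(-lambda * (t^shape - (t - 1)^shape))
}

#' Closed-form cumulative incidence
#'
#' \eqn{1 - \exp(-\lambda w^k)}: probability of at least one event within
#' `w` weeks. Used as the analytic oracle for the simulation engine.
#'
#' @param lambda Weibull scale(s).
#' @param shape Weibull shape `k`.
#' @param w Weeks (>= 0).
#' @return Probability/ies.
#' @export
cumulative_incidence <- function(lambda, shape, w) {
  if (any(w < 0)) stop("'w' must be non-negative", call. = FALSE)
  -expm1(-lambda * w^shape)
}
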