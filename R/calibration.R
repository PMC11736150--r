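#' Calibration targets
#'
#' Direct constructor for the three percentage targets the reference
#' scenario is calibrated to. Usually built from registry counts via
#' [registry_targets_from_counts()]; the direct form exists for synthetic
#' (self-generated) targets, e.g. parameter-recovery checks.
#'
#' @param mortality_target_pct,hospitalization_target_pct,urgent_share_target_pct
#'   Targets in percent, each in (0, 100).
#' @param tolerance_pp Calibration tolerance in percentage points.
#' @return An object of class `calibration_targets`.
#' @export
calibration_targets <- function(mortality_target_pct,
                                hospitalization_target_pct,
                                urgent_share_target_pct,
                                tolerance_pp = 0.1) {
  v <- c(mortality_target_pct, hospitalization_target_pct,
         urgent_share_target_pct)
  if (any(v <= 0 | v >= 100))
    stop("targets must lie strictly inside (0, 100) percent", call. = FALSE)
  if (tolerance_pp <= 0) stop("'tolerance_pp' must be positive",
                              call. = FALSE)
  structure(list(mortality_target_pct = mortality_target_pct,
                 hospitalization_target_pct = hospitalization_target_pct,
                 urgent_share_target_pct = urgent_share_target_pct,
                 tolerance_pp = tolerance_pp,
                 counts = NULL),
            class = "calibration_targets")
}

#' Calibration targets from registry counts
#'
#' Converts printed registry tallies for one fiscal year into the three
#' percentage targets the reference scenario is calibrated to. Denominators:
#' mortality and hospitalization are out of the referrals that stayed on the
#' list (referrals minus removals); the urgent share is out of all
#' procedures performed.
#'
#' @param referrals Patients referred.
#' @param removed Patients removed from the waitlist (not modelled as an
#'   event; they only shrink the denominator).
#' @param tavis Procedures performed.
#' @param deaths Waitlist deaths.
#' @param hospitalized Patients with at least one unplanned hospitalization.
#' @param unscheduled Urgent (unscheduled) procedures.
#' @param tolerance_pp Calibration tolerance in percentage points
#'   (default 0.1).
#' @return An object of class `calibration_targets` with fields
#'   `mortality_target_pct`, `hospitalization_target_pct`,
#'   `urgent_share_target_pct`, `tolerance_pp`.
#' @examples
#' registry_targets_from_counts(3030, 803, 1330, 81, 756, 202)
#' # 3.6% mortality, 33.9% hospitalization, 15.2% urgent share
#' @export
registry_targets_from_counts <- function(referrals, removed, tavis, deaths,
                                         hospitalized, unscheduled,
                                         tolerance_pp = 0.1) {
  counts <- c(referrals = referrals, removed = removed, tavis = tavis,
              deaths = deaths, hospitalized = hospitalized,
              unscheduled = unscheduled)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (removed >= referrals)
    stop("'removed' must be smaller than 'referrals'", call. = FALSE)
  if (unscheduled > tavis)
    stop("'unscheduled' cannot exceed 'tavis'", call. = FALSE)
  if (tavis == 0) stop("zero procedures: urgent share undefined",
                       call. = FALSE)
  if (tolerance_pp <= 0) stop("'tolerance_pp' must be positive",
                              call. = FALSE)
  denom <- referrals - removed
  structure(list(mortality_target_pct = 100 * deaths / denom,
                 hospitalization_target_pct = 100 * hospitalized / denom,
                 urgent_share_target_pct = 100 * unscheduled / tavis,
                 tolerance_pp = tolerance_pp,
                 counts = counts),
            class = "calibration_targets")
}

#' @export
print.calibration_targets <- function(x, ...) {
  cat("Calibration targets (registry counts)\n")
  cat(sprintf("  mortality %.1f%%  hospitalization %.1f%%  urgent share %.1f%%  (tol %.2f pp)\n",
              x$mortality_target_pct, x$hospitalization_target_pct,
              x$urgent_share_target_pct, x$tolerance_pp))
  invisible(x)
}

#' Calibrate hazard multipliers to registry targets
#'
#' Tunes the three multipliers of [hazard_params()] so the reference
#' (first-come-first-served) scenario reproduces the registry targets.
#' Sequential one-dimensional monotone root-finding on the log-multiplier,
#' in the order hospitalization -> urgent share -> mortality (urgent share
#' rides on the hospitalization flow, and mortality is only weakly coupled
#' to both through exposure truncation), repeated for up to `max_sweeps`
#' outer sweeps. Every evaluation is a reduced-replicate simulation with
#' common random numbers, so the objective is a deterministic, monotone
#' function of each multiplier and bracketing root-finding applies.
#'
#' @param targets A [registry_targets_from_counts()] object.
#' @param spec A reference-scheme [scenario_spec()] used as the evaluation
#'   template; its `n_replicates` is typically reduced (default template in
#'   [taviwait_defaults()] uses 20).
#' @param max_sweeps Outer sweeps over the three multipliers (default 5).
#' @param mult_bounds Search interval for every multiplier (default
#'   `c(1e-3, 1e3)`).
#' @return A `calibration_result`: `hazards` (fitted [hazard_params()]),
#'   `achieved` (outcome percentages at the fit, from the evaluation seeds),
#'   `iterations` (simulation evaluations used), `converged`, `trace`
#'   (per-sweep residuals, in pp).
#' @export
calibrate_reference <- function(targets, spec, max_sweeps = 5L,
                                mult_bounds = c(1e-3, 1e3)) {
  stopifnot(inherits(targets, "calibration_targets"),
            inherits(spec, "scenario_spec"))
  if (!spec$scheme$reference)
    stop("calibration requires the reference (single-tier) scheme",
         call. = FALSE)
  prepared <- .prepare_replicates(spec)
  hz <- spec$hazards
  n_eval <- 0L
  evaluate <- function(hz) {
    n_eval <<- n_eval + 1L
    s <- .run_prepared(prepared, hz)
    c(hosp = s$hospitalization_pct, urgent = s$urgent_pct,
      death = s$mortality_pct)
  }
  goal <- c(hosp = targets$hospitalization_target_pct,
            urgent = targets$urgent_share_target_pct,
            death = targets$mortality_target_pct)
  mult_field <- c(hosp = "mult_hosp", urgent = "mult_urgent",
                  death = "mult_death")
  tol <- targets$tolerance_pp
  trace <- list()
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (nm in c("hosp", "urgent", "death")) {
      f <- function(logc) {
        h <- hz
        h[[mult_field[[nm]]]] <- exp(logc)
        evaluate(h)[[nm]] - goal[[nm]]
      }
      lo <- log(mult_bounds[1]); hi <- log(mult_bounds[2])
      flo <- f(lo); fhi <- f(hi)
      if (flo > 0 || fhi < 0)
        stop(sprintf(paste0("calibration target for '%s' unreachable: ",
                            "outcome spans [%.3f, %.3f]%% over the ",
                            "multiplier bounds, target %.3f%%"),
                     nm, flo + goal[[nm]], fhi + goal[[nm]], goal[[nm]]),
             call. = FALSE)
      root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                             tol = 1e-5)
      hz[[mult_field[[nm]]]] <- exp(root$root)
    }
    achieved <- evaluate(hz)
    resid <- achieved - goal
    trace[[sweep]] <- resid
    if (all(abs(resid) <= tol)) { converged <- TRUE; break }
  }
  if (!converged) {
    resid <- trace[[length(trace)]]
    stop(sprintf(paste0("calibration did not converge after %d sweeps; ",
                        "residuals (pp): hosp %.3f, urgent %.3f, ",
                        "death %.3f"),
                 length(trace), resid[["hosp"]], resid[["urgent"]],
                 resid[["death"]]), call. = FALSE)
  }
  structure(list(hazards = hz,
                 achieved = achieved,
                 targets = targets,
                 iterations = n_eval,
                 converged = converged,
                 trace = trace),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration %s after %d simulation evaluations (%d sweeps)\n",
              if (x$converged) "converged" else "FAILED", x$iterations,
              length(x$trace)))
  cat(sprintf("  multipliers: death %.4f, hosp %.4f, urgent %.4f\n",
              x$hazards$mult_death, x$hazards$mult_hosp,
              x$hazards$mult_urgent))
  cat(sprintf("  achieved   : mortality %.2f%%, hospitalization %.2f%%, urgent %.2f%%\n",
              x$achieved[["death"]], x$achieved[["hosp"]],
              x$achieved[["urgent"]]))
  invisible(x)
}
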