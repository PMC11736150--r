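# Weekly-cycle closed-cohort engine. All randomness flows through three
# integer sub-seeds per replicate (cohort / assignment / events) derived from
# the scenario seed, and the engine draws one uniform per patient per event
# type per week for the FULL cohort regardless of status. Two scenarios
# sharing a seed therefore see identical cohorts and identical event
# uniforms, and differ only through assigned waits (common random numbers).

.sub_seed <- function(seed, replicate, stream) {
  as.integer((as.double(seed %% 100000L) * 48271 +
              as.double(replicate) * 1299721 + stream * 7919) %% 2147483629)
}

#' Scenario specification
#'
#' Bundles everything one simulated scenario needs: the synthetic
#' population, the prioritization scheme, the hazard parameters, the
#' capacity budget, and the replication plan.
#'
#' @param population A [population_params()] object (its `n_patients` and
#'   `seed` are overridden per replicate by `patients_per_replicate` and the
#'   scenario seed).
#' @param scheme A [group_scheme()] or [reference_scheme()].
#' @param hazards A [hazard_params()] object.
#' @param constraint A [budget_constraint()].
#' @param n_replicates Simulation replicates to average over (default 100).
#' @param patients_per_replicate Cohort size per replicate (default 50000).
#' @param seed Top-level integer seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(population = population_params(),
                          scheme = reference_scheme(),
                          hazards = hazard_params(),
                          constraint = budget_constraint(),
                          n_replicates = 100L,
                          patients_per_replicate = 50000L,
                          seed = 1L) {
  stopifnot(inherits(population, "population_params"),
            inherits(scheme, "group_scheme"),
            inherits(hazards, "hazard_params"),
            inherits(constraint, "budget_constraint"))
  n_replicates <- as.integer(n_replicates)
  patients_per_replicate <- as.integer(patients_per_replicate)
  if (n_replicates < 1L || patients_per_replicate < 1L)
    stop("'n_replicates' and 'patients_per_replicate' must be >= 1",
         call. = FALSE)
  structure(list(population = population, scheme = scheme, hazards = hazards,
                 constraint = constraint, n_replicates = n_replicates,
                 patients_per_replicate = patients_per_replicate,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Simulate one replicate of the waitlist
#'
#' Follows every patient week by week until the waitlist empties. Within a
#' week, in order: (1) death trial at the patient's weekly Weibull death
#' probability; (2) if alive, hospitalization trial; (3) a hospitalized
#' patient converts to an urgent procedure with probability
#' `min(1, mult_urgent * p_urgent_given_hosp)` and exits; (4) survivors
#' whose assigned wait elapses exit by elective procedure. Death,
#' hospitalization (recurrent) and urgent conversion stop once a patient
#' exits; deaths + urgent + elective always equal the cohort size.
#'
#' @param cohort A `cohort`.
#' @param assignment A [assign_wait_times()] result for that cohort.
#' @param hazards A [hazard_params()].
#' @param seed Integer seed for the weekly event draws.
#' @return An `outcome_summary` for the single replicate: waitlist
#'   mortality, hospitalization (patients with >= 1 admission) and urgent
#'   share of procedures (all in percent), realized and per-tier waits, and
#'   raw counts.
#' @export
simulate_cohort <- function(cohort, assignment, hazards, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(assignment, "wait_assignment"),
            inherits(hazards, "hazard_params"))
  pr <- cohort$profiles
  n <- nrow(pr)
  w <- assignment$wait_weeks
  if (length(w) != n)
    stop("assignment does not match the cohort", call. = FALSE)
  kd <- hazards$shape_death
  kh <- hazards$shape_hosp
  lam_d <- weibull_scale_from_risk(pr$p_death12, kd, hazards$risk_horizon,
                                   hazards$mult_death)
  lam_h <- weibull_scale_from_risk(pr$p_hosp12, kh, hazards$risk_horizon,
                                   hazards$mult_hosp)
  p_urg <- pmin(1, hazards$mult_urgent * pr$p_urgent_given_hosp)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  waiting <- rep(TRUE, n)
  dead <- urgent <- elective <- ever_hosp <- rep(FALSE, n)
  exit_week <- integer(n)
  for (t in seq_len(max(w))) {
    q_d <- -expm1(-lam_d * (t^kd - (t - 1)^kd))
    q_h <- -expm1(-lam_h * (t^kh - (t - 1)^kh))
    u_d <- stats::runif(n)
    u_h <- stats::runif(n)
    u_u <- stats::runif(n)
    died_now <- waiting & (u_d < q_d)
    dead[died_now] <- TRUE
    exit_week[died_now] <- t
    alive <- waiting & !died_now
    hosp_now <- alive & (u_h < q_h)
    ever_hosp <- ever_hosp | hosp_now
    urgent_now <- hosp_now & (u_u < p_urg)
    urgent[urgent_now] <- TRUE
    exit_week[urgent_now] <- t
    elective_now <- alive & !urgent_now & (w == t)
    elective[elective_now] <- TRUE
    exit_week[elective_now] <- t
    waiting <- alive & !urgent_now & !elective_now
    if (!any(waiting)) break
  }
  n_tavi <- sum(urgent) + sum(elective)
  per_group <- tapply(w, assignment$group, mean)
  outcome_summary(
    mortality_pct = 100 * sum(dead) / n,
    hospitalization_pct = 100 * sum(ever_hosp) / n,
    urgent_pct = if (n_tavi > 0) 100 * sum(urgent) / n_tavi else 0,
    mean_realized_wait = mean(exit_week),
    mean_assigned_wait = mean(w),
    per_group_waits = per_group,
    counts = c(n = n, deaths = sum(dead), urgent = sum(urgent),
               elective = sum(elective), hospitalized = sum(ever_hosp)),
    n_replicates = 1L)
}

#' Construct an outcome summary
#'
#' @param mortality_pct,hospitalization_pct,urgent_pct Headline outcomes in
#'   percent of cohort (mortality, >= 1 hospitalization) and of procedures
#'   performed (urgent share).
#' @param mean_realized_wait Mean week of exit (death or procedure).
#' @param mean_assigned_wait Mean assigned wait.
#' @param per_group_waits Named vector of mean assigned waits per tier.
#' @param counts Named vector of raw tallies.
#' @param n_replicates Number of replicates the summary averages over.
#' @param se Named vector of Monte-Carlo standard errors (NA for a single
#'   replicate).
#' @return An object of class `outcome_summary`.
#' @export
outcome_summary <- function(mortality_pct, hospitalization_pct, urgent_pct,
                            mean_realized_wait, mean_assigned_wait,
                            per_group_waits, counts, n_replicates = 1L,
                            se = c(mortality_pct = NA_real_,
                                   hospitalization_pct = NA_real_,
                                   urgent_pct = NA_real_)) {
  structure(list(mortality_pct = mortality_pct,
                 hospitalization_pct = hospitalization_pct,
                 urgent_pct = urgent_pct,
                 mean_realized_wait = mean_realized_wait,
                 mean_assigned_wait = mean_assigned_wait,
                 per_group_waits = per_group_waits,
                 counts = counts,
                 n_replicates = n_replicates,
                 se = se),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Waitlist outcomes (%d replicate%s)\n", x$n_replicates,
              if (x$n_replicates == 1L) "" else "s"))
  fmt <- function(v, s) if (is.na(s)) sprintf("%.2f%%", v)
                        else sprintf("%.2f%% (SE %.3f)", v, s)
  cat("  mortality      : ", fmt(x$mortality_pct, x$se[["mortality_pct"]]),
      "\n  hospitalization: ",
      fmt(x$hospitalization_pct, x$se[["hospitalization_pct"]]),
      "\n  urgent share   : ", fmt(x$urgent_pct, x$se[["urgent_pct"]]),
      "\n", sep = "")
  cat(sprintf("  mean realized wait: %.2f weeks (assigned %.2f)\n",
              x$mean_realized_wait, x$mean_assigned_wait))
  invisible(x)
}

#' Average outcome summaries across replicates
#'
#' Unweighted means of every outcome; Monte-Carlo standard error is the
#' sample standard deviation across replicates divided by the square root of
#' the replicate count (undefined for a single replicate).
#'
#' @param summaries A non-empty list of `outcome_summary` objects.
#' @return An aggregated `outcome_summary`.
#' @export
aggregate_replicates <- function(summaries) {
  if (length(summaries) == 0L)
    stop("need at least one replicate to aggregate", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "outcome_summary")))
  r <- length(summaries)
  pull <- function(f) vapply(summaries, `[[`, numeric(1), f)
  se_of <- function(x) if (r > 1L) stats::sd(x) / sqrt(r) else NA_real_
  mort <- pull("mortality_pct")
  hosp <- pull("hospitalization_pct")
  urg <- pull("urgent_pct")
  pg <- Reduce(`+`, lapply(summaries, `[[`, "per_group_waits")) / r
  counts <- Reduce(`+`, lapply(summaries, `[[`, "counts"))
  outcome_summary(
    mortality_pct = mean(mort),
    hospitalization_pct = mean(hosp),
    urgent_pct = mean(urg),
    mean_realized_wait = mean(pull("mean_realized_wait")),
    mean_assigned_wait = mean(pull("mean_assigned_wait")),
    per_group_waits = pg,
    counts = counts,
    n_replicates = r,
    se = c(mortality_pct = se_of(mort), hospitalization_pct = se_of(hosp),
           urgent_pct = se_of(urg)))
}

# Pre-build the hazard-independent part of every replicate (cohort,
# assignment, event seed) so calibration can re-evaluate many multiplier
# settings without resampling.
.prepare_replicates <- function(spec) {
  lapply(seq_len(spec$n_replicates), function(r) {
    pop <- spec$population
    pop$n_patients <- spec$patients_per_replicate
    pop$seed <- .sub_seed(spec$seed, r, 1L)
    coh <- sample_cohort(pop)
    assign_seed <- .sub_seed(spec$seed, r, 2L)
    asg <- assign_wait_times(coh, spec$scheme, spec$constraint,
                             seed = assign_seed)
    list(replicate = r, cohort = coh, assignment = asg,
         assign_seed = assign_seed,
         event_seed = .sub_seed(spec$seed, r, 3L))
  })
}

.run_prepared <- function(prepared, hazards) {
  aggregate_replicates(lapply(prepared, function(p)
    simulate_cohort(p$cohort, p$assignment, hazards, seed = p$event_seed)))
}

#' Run a scenario (all replicates) and aggregate
#'
#' Samples a fresh cohort per replicate, assigns waits, simulates, and
#' averages. Deterministic given `spec$seed`.
#'
#' @param spec A [scenario_spec()].
#' @return An aggregated `outcome_summary`.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .run_prepared(.prepare_replicates(spec), spec$hazards)
}
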