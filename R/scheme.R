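#' Risk-tier scheme and capacity budget
#'
#' A `group_scheme` fixes the tier sizes (fractions of the cohort, ordered
#' high -> low risk) and the wait-times of the prioritized tiers; the
#' non-prioritized (last) tier's wait is never set directly but solved from
#' the capacity budget: the size-weighted mean wait across tiers must equal
#' the system's status-quo mean (12.5 weeks in Ontario), representing fixed
#' procedural capacity. A `reference_scheme()` is the status-quo
#' first-come-first-served anchor: a single tier at the target mean.
#'
#' @param sizes Tier fractions, high -> low, summing to 1 (tolerance 1e-9);
#'   length 2 or 3.
#' @param waits_prioritized Wait-time in whole weeks for every tier except
#'   the last; length `length(sizes) - 1`.
#' @param classifier_outcome What drives classification: `"latent"` (the
#'   severity quantile; default) or one risk margin (`"death"`, `"hosp"`,
#'   `"urgent"`). Under the comonotone population these coincide.
#' @return An object of class `group_scheme`.
#' @export
group_scheme <- function(sizes, waits_prioritized,
                         classifier_outcome = c("latent", "death", "hosp",
                                                "urgent")) {
  classifier_outcome <- match.arg(classifier_outcome)
  if (!is.numeric(sizes) || !(length(sizes) %in% c(2L, 3L)))
    stop("'sizes' must be a numeric vector of length 2 or 3", call. = FALSE)
  if (any(sizes <= 0)) stop("tier sizes must be positive", call. = FALSE)
  if (abs(sum(sizes) - 1) > 1e-9)
    stop("tier sizes must sum to 1", call. = FALSE)
  if (length(waits_prioritized) != length(sizes) - 1L)
    stop("need one prioritized wait per tier except the last", call. = FALSE)
  if (any(waits_prioritized <= 0))
    stop("prioritized waits must be positive", call. = FALSE)
  if (is.unsorted(waits_prioritized, strictly = TRUE) &&
      length(waits_prioritized) > 1L)
    stop("prioritized waits must increase from high to lower tiers",
         call. = FALSE)
  structure(list(n_groups = length(sizes),
                 sizes = as.numeric(sizes),
                 waits_prioritized = as.numeric(waits_prioritized),
                 classifier_outcome = classifier_outcome,
                 reference = FALSE),
            class = "group_scheme")
}

#' @rdname group_scheme
#' @export
reference_scheme <- function() {
  structure(list(n_groups = 1L, sizes = 1, waits_prioritized = numeric(0),
                 classifier_outcome = "latent", reference = TRUE),
            class = "group_scheme")
}

#' @export
print.group_scheme <- function(x, ...) {
  if (x$reference) {
    cat("Reference scheme (first-come-first-served, single tier)\n")
  } else {
    lab <- .group_labels(x$n_groups)
    cat(sprintf("%d-tier prioritization scheme (classifier: %s)\n",
                x$n_groups, x$classifier_outcome))
    cat(sprintf("  %-6s size %4.1f%%  wait %s\n", lab,
                100 * x$sizes,
                c(format(x$waits_prioritized), "solved")), sep = "")
  }
  invisible(x)
}

#' Capacity budget constraint
#'
#' @param target_mean_wait Cohort-mean assigned wait in weeks (> 0);
#'   default 12.5, the Ontario status-quo mean.
#' @return An object of class `budget_constraint`.
#' @export
budget_constraint <- function(target_mean_wait = 12.5) {
  if (!is.numeric(target_mean_wait) || length(target_mean_wait) != 1L ||
      target_mean_wait <= 0)
    stop("'target_mean_wait' must be a positive number", call. = FALSE)
  structure(list(target_mean_wait = target_mean_wait),
            class = "budget_constraint")
}

.group_labels <- function(n_groups) {
  switch(n_groups, "all", c("high", "low"), c("high", "medium", "low"))
}

#' Solve the non-prioritized tier's wait from the capacity budget
#'
#' Closed form: with tier fractions \eqn{p_g} and prioritized waits
#' \eqn{w_g}, the low tier's wait is
#' \deqn{w_{low} = (\bar W - \sum_{g} p_g w_g) / p_{low}}
#' so that the size-weighted mean equals the target \eqn{\bar W} exactly.
#'
#' A non-positive solution is an infeasible scheme (error). A solution not
#' exceeding the longest prioritized wait violates the high-to-low ordering;
#' it is returned with a warning so grid enumeration can still tabulate the
#' corner.
#'
#' @param sizes Tier fractions, high -> low, summing to 1.
#' @param waits_prioritized Waits for all tiers but the last (may be empty
#'   for a single-tier scheme, in which case the target itself is returned).
#' @param constraint A [budget_constraint()].
#' @return Solved low-tier wait in (continuous) weeks.
#' @examples
#' solve_low_risk_wait(c(0.30, 0.30, 0.40), c(3, 5), budget_constraint())
#' # 25.25 -> reported as 25 weeks
#' @export
solve_low_risk_wait <- function(sizes, waits_prioritized,
                                constraint = budget_constraint()) {
  stopifnot(inherits(constraint, "budget_constraint"))
  if (abs(sum(sizes) - 1) > 1e-9)
    stop("tier sizes must sum to 1", call. = FALSE)
  if (any(sizes <= 0)) stop("tier sizes must be positive", call. = FALSE)
  k <- length(sizes)
  if (length(waits_prioritized) != k - 1L)
    stop("need one prioritized wait per tier except the last", call. = FALSE)
  wbar <- constraint$target_mean_wait
  if (k == 1L) return(wbar)
  if (any(waits_prioritized <= 0))
    stop("prioritized waits must be positive", call. = FALSE)
  p_low <- sizes[k]
  w_low <- (wbar - sum(sizes[-k] * waits_prioritized)) / p_low
  if (w_low <= 0)
    stop(sprintf(paste0("infeasible scheme: solved low-risk wait %.3f weeks ",
                        "is not positive under the %.1f-week budget"),
                 w_low, wbar), call. = FALSE)
  if (w_low <= max(waits_prioritized))
    warning(sprintf(paste0("ordering violation: solved low-risk wait %.2f ",
                           "weeks does not exceed the longest prioritized ",
                           "wait (%.0f weeks)"),
                    w_low, max(waits_prioritized)), call. = FALSE)
  w_low
}

#' Classify a cohort into risk tiers
#'
#' Ranks patients by the scheme's classifier (latent severity quantile by
#' default) and fills tiers from the top: the highest-risk
#' `round(n * sizes[1])` patients are `high`, the next block `medium` (when
#' present), the remainder `low`. Ties are broken by ascending `patient_id`
#' for reproducibility; tier counts differ from `n * size` by at most one
#' patient.
#'
#' @param cohort A [sample_cohort()] cohort.
#' @param scheme A [group_scheme()].
#' @return Factor of tier labels (levels high/medium/low as applicable),
#'   aligned with `cohort$profiles`.
#' @export
classify_cohort <- function(cohort, scheme) {
  stopifnot(inherits(cohort, "cohort"), inherits(scheme, "group_scheme"))
  n <- nrow(cohort$profiles)
  if (scheme$reference)
    return(factor(rep("all", n), levels = "all"))
  if (n < scheme$n_groups)
    stop("cohort smaller than the number of tiers", call. = FALSE)
  x <- switch(scheme$classifier_outcome,
              latent = cohort$profiles$u_latent,
              death = cohort$profiles$p_death12,
              hosp = cohort$profiles$p_hosp12,
              urgent = cohort$profiles$p_urgent_given_hosp)
  ord <- order(-x, cohort$profiles$patient_id)
  counts <- round(n * scheme$sizes)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  lab <- .group_labels(scheme$n_groups)
  labels <- rep(lab, counts)
  out <- character(n)
  out[ord] <- labels
  factor(out, levels = lab)
}

#' Assign wait-times under the capacity budget
#'
#' Prioritized tiers receive their configured integer week verbatim. The low
#' tier's solved wait is generally fractional; each low-tier patient is
#' randomized between the two adjacent whole weeks, with the ceiling drawn
#' with probability equal to the fractional part, so the cohort-mean
#' assigned wait equals the budget target exactly in expectation. The
#' reference scheme mixes 12 and 13 weeks at 0.5 each (target 12.5).
#'
#' @param cohort A `cohort`.
#' @param scheme A [group_scheme()] (or [reference_scheme()]).
#' @param constraint A [budget_constraint()].
#' @param seed Integer seed for the fractional-week randomization.
#' @return A `wait_assignment`: list with `group` (factor), `wait_weeks`
#'   (integer per patient), `solved_low_wait` (continuous weeks), `scheme`,
#'   `constraint`.
#' @export
assign_wait_times <- function(cohort, scheme,
                              constraint = budget_constraint(),
                              seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  group <- classify_cohort(cohort, scheme)
  n <- length(group)
  w_low <- withCallingHandlers(
    solve_low_risk_wait(scheme$sizes, scheme$waits_prioritized, constraint),
    warning = function(w) invokeRestart("muffleWarning"))
  waits <- numeric(n)
  lab <- levels(group)
  k <- length(lab)
  if (k > 1L)
    for (g in seq_len(k - 1L))
      waits[group == lab[g]] <- scheme$waits_prioritized[g]
  low <- group == lab[k]
  lo <- floor(w_low)
  frac <- w_low - lo
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  waits[low] <- lo + (stats::runif(sum(low)) < frac)
  if (lo == 0) waits[low] <- pmax(waits[low], 1)  # degenerate sub-week solve
  structure(list(group = group,
                 wait_weeks = as.integer(waits),
                 solved_low_wait = w_low,
                 scheme = scheme,
                 constraint = constraint),
            class = "wait_assignment")
}

#' @export
print.wait_assignment <- function(x, ...) {
  cat(sprintf("Wait assignment: %d patients, mean %.3f weeks (target %.2f)\n",
              length(x$wait_weeks), mean(x$wait_weeks),
              x$constraint$target_mean_wait))
  tb <- table(x$group)
  for (g in names(tb))
    cat(sprintf("  %-6s n=%6d  mean wait %.2f\n", g, tb[[g]],
                mean(x$wait_weeks[x$group == g])))
  invisible(x)
}

#' Write a wait assignment as CSV (patient_id, group, assigned_wait_weeks)
#' @param assignment A `wait_assignment`.
#' @param cohort The cohort it was built from.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assignment_csv <- function(assignment, cohort, path) {
  utils::write.csv(data.frame(patient_id = cohort$profiles$patient_id,
                              group = as.character(assignment$group),
                              assigned_wait_weeks = assignment$wait_weeks),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
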