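#' Population parameters for the synthetic referral cohort
#'
#' Describes the joint distribution of 12-week predicted risks across a
#' referred TAVI population. Each of the three outcome margins (all-cause
#' death, all-cause hospitalization, and urgent-procedure conversion given a
#' hospitalization) follows a Beta distribution parameterized by its mean and
#' a dispersion; all three margins are driven comonotonically by a single
#' latent severity quantile, so one ordering of patients by severity induces
#' the ordering on every margin.
#'
#' The Beta margin for mean \eqn{m} and dispersion \eqn{d} uses concentration
#' \eqn{s = 1/d}, shapes \eqn{a = m s}, \eqn{b = (1 - m) s}. Larger dispersion
#' means smaller concentration, hence a heavier right tail (for means below
#' 1/2). Defaults echo the Ontario registry proportions, with the
#' urgent-conversion margin the most right-skewed of the three; they are
#' implementation defaults, not registry estimates.
#'
#' @param n_patients Number of patients in a sampled cohort (>= 1).
#' @param mean_death12 Mean 12-week predicted risk of death, in (0, 1).
#'   Degenerate value 0 is accepted and yields all-zero risks.
#' @param mean_hosp12 Mean 12-week predicted risk of hospitalization.
#' @param mean_urgent_given_hosp Mean probability that a hospitalization
#'   converts to an urgent procedure.
#' @param dispersion_death,dispersion_hosp,dispersion_urgent Positive
#'   dispersion of each margin; larger is more right-skewed.
#' @param seed Integer seed making [sample_cohort()] deterministic.
#' @return An object of class `population_params`.
#' @seealso [sample_cohort()], [marginal_quantile()]
#' @export
population_params <- function(n_patients = 50000L,
                              mean_death12 = 0.036,
                              mean_hosp12 = 0.34,
                              mean_urgent_given_hosp = 0.10,
                              dispersion_death = 0.05,
                              dispersion_hosp = 0.5,
                              dispersion_urgent = 5,
                              seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L)
    stop("invalid population parameter 'n_patients': must be an integer >= 1",
         call. = FALSE)
  means <- c(mean_death12 = mean_death12, mean_hosp12 = mean_hosp12,
             mean_urgent_given_hosp = mean_urgent_given_hosp)
  for (nm in names(means)) {
    m <- means[[nm]]
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m >= 1)
      stop(sprintf("invalid population parameter '%s': must be in [0, 1)", nm),
           call. = FALSE)
  }
  disps <- c(dispersion_death = dispersion_death,
             dispersion_hosp = dispersion_hosp,
             dispersion_urgent = dispersion_urgent)
  for (nm in names(disps)) {
    d <- disps[[nm]]
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0)
      stop(sprintf("invalid population parameter '%s': must be > 0", nm),
           call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid population parameter 'seed'", call. = FALSE)
  structure(list(n_patients = n_patients,
                 mean_death12 = mean_death12,
                 mean_hosp12 = mean_hosp12,
                 mean_urgent_given_hosp = mean_urgent_given_hosp,
                 dispersion_death = dispersion_death,
                 dispersion_hosp = dispersion_hosp,
                 dispersion_urgent = dispersion_urgent,
                 seed = seed),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Synthetic TAVI referral population\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  death12   : mean %.4f  dispersion %.3g\n",
              x$mean_death12, x$dispersion_death))
  cat(sprintf("  hosp12    : mean %.4f  dispersion %.3g\n",
              x$mean_hosp12, x$dispersion_hosp))
  cat(sprintf("  urgent|h  : mean %.4f  dispersion %.3g\n",
              x$mean_urgent_given_hosp, x$dispersion_urgent))
  invisible(x)
}

# Beta shapes (a, b) for one margin; mean 0 collapses to a point mass at 0,
# handled by callers.
.beta_shapes <- function(mean, dispersion) {
  s <- 1 / dispersion
  c(a = mean * s, b = (1 - mean) * s)
}

.margin_pars <- function(params, outcome) {
  switch(outcome,
    death  = c(mean = params$mean_death12,  disp = params$dispersion_death),
    hosp   = c(mean = params$mean_hosp12,   disp = params$dispersion_hosp),
    urgent = c(mean = params$mean_urgent_given_hosp,
               disp = params$dispersion_urgent),
    stop("unknown outcome '", outcome, "' (use death, hosp or urgent)",
         call. = FALSE))
}

#' Inverse CDF of one risk margin
#'
#' Evaluates the configured Beta margin's quantile function at latent
#' severity quantile `u`. This is the map each sampled patient's `u_latent`
#' is pushed through, so population percentiles of predicted risk are read
#' off directly (e.g. `u = 0.90` is the classification threshold when the
#' high-risk tier is 10% of the cohort).
#'
#' @param params A [population_params()] object.
#' @param outcome One of `"death"`, `"hosp"`, `"urgent"`.
#' @param u Quantile(s) strictly inside (0, 1).
#' @return Predicted risk at the requested quantile(s).
#' @export
marginal_quantile <- function(params, outcome = c("death", "hosp", "urgent"),
                              u) {
  outcome <- match.arg(outcome)
  if (!is.numeric(u) || any(is.na(u)) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1)", call. = FALSE)
  mp <- .margin_pars(params, outcome)
  if (mp[["mean"]] == 0) return(rep(0, length(u)))
  sh <- .beta_shapes(mp[["mean"]], mp[["disp"]])
  # qbeta warns about limited precision in the far tails of very
  # low-concentration shapes; the residual error there is far below any
  # quantity of interest, so muffle that specific warning only
  withCallingHandlers(
    stats::qbeta(u, sh[["a"]], sh[["b"]]),
    warning = function(w) {
      if (grepl("full precision may not have been achieved",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Sample a synthetic referral cohort
#'
#' Draws `n_patients` latent severity quantiles `u_latent ~ U(0,1)` and
#' evaluates each risk margin's inverse CDF at them (comonotone coupling:
#' a sicker patient is sicker on every margin). Deterministic given
#' `params$seed`; the caller's RNG state is preserved.
#'
#' @param params A [population_params()] object.
#' @return A `cohort`: list with `profiles` (data.frame with columns
#'   `patient_id`, `u_latent`, `p_death12`, `p_hosp12`,
#'   `p_urgent_given_hosp`) and `params` (provenance).
#' @examples
#' coh <- sample_cohort(population_params(n_patients = 100, seed = 7))
#' head(coh$profiles)
#' @export
sample_cohort <- function(params) {
  stopifnot(inherits(params, "population_params"))
  n <- params$n_patients
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(params$seed)
  u <- stats::runif(n)
  # clamp away from the endpoints so every margin stays inside (0, 1)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  # clamp sampled risks inside (0, 1): with heavy-tailed margins qbeta can
  # round to exactly 0 or 1 at extreme latent quantiles
  clamp <- function(x, m) if (m == 0) x else pmin(pmax(x, 1e-15), 1 - 1e-12)
  profiles <- data.frame(
    patient_id = seq_len(n),
    u_latent = u,
    p_death12 = clamp(marginal_quantile(params, "death", u),
                      params$mean_death12),
    p_hosp12 = clamp(marginal_quantile(params, "hosp", u),
                     params$mean_hosp12),
    p_urgent_given_hosp = clamp(marginal_quantile(params, "urgent", u),
                                params$mean_urgent_given_hosp))
  structure(list(profiles = profiles, params = params), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("TAVI referral cohort: %d patients (seed %d)\n",
              nrow(x$profiles), x$params$seed))
  cat(sprintf("  mean p_death12 %.4f, mean p_hosp12 %.4f, mean p_urgent|h %.4f\n",
              mean(x$profiles$p_death12), mean(x$profiles$p_hosp12),
              mean(x$profiles$p_urgent_given_hosp)))
  invisible(x)
}

#' Empirical percentile threshold for a risk tier
#'
#' Returns the predicted-risk value such that the top `top_fraction` of the
#' cohort (by the chosen margin) lies at or above it: the nearest-rank
#' (ceiling) empirical `1 - top_fraction` quantile. With tier size 10% this
#' is the 90th percentile of the margin's distribution in the cohort.
#'
#' @param cohort A [sample_cohort()] result.
#' @param outcome Margin to threshold: `"death"`, `"hosp"` or `"urgent"`.
#' @param top_fraction Tier size as a fraction of the cohort, in (0, 1).
#' @return The threshold risk (scalar).
#' @export
risk_percentile_threshold <- function(cohort,
                                      outcome = c("death", "hosp", "urgent"),
                                      top_fraction) {
  stopifnot(inherits(cohort, "cohort"))
  outcome <- match.arg(outcome)
  if (nrow(cohort$profiles) == 0L) stop("empty cohort", call. = FALSE)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1)
    stop("'top_fraction' must lie strictly inside (0, 1)", call. = FALSE)
  x <- switch(outcome,
              death = cohort$profiles$p_death12,
              hosp = cohort$profiles$p_hosp12,
              urgent = cohort$profiles$p_urgent_given_hosp)
  n <- length(x)
  # nearest-rank: smallest x with at least ceiling(n * (1 - top_fraction))
  # observations at or below it
  k <- ceiling(n * (1 - top_fraction))
  k <- min(max(k, 1L), n)
  sort(x, partial = k)[k]
}

#' Write / read a cohort as CSV
#'
#' Columns `patient_id, u_latent, p_death12, p_hosp12, p_urgent_given_hosp`,
#' header required, full double precision (17 significant digits).
#'
#' @param cohort A `cohort` object.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort` (with `params = NULL` provenance).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cohort$profiles
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("patient_id", "u_latent", "p_death12", "p_hosp12",
            "p_urgent_given_hosp")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(profiles = df[need], params = NULL), class = "cohort")
}

# Save/restore .Random.seed so seeded sampling does not clobber the caller.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
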