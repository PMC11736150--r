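#' Default configuration
#'
#' One nested list drives every pipeline stage; blocks mirror the
#' constructor argument names exactly. Values here are implementation
#' defaults for the synthetic world (the registry's empirical risk
#' distribution is not released): margin means echo the registry
#' proportions and the dispersions make the urgent-conversion margin the
#' most right-skewed of the three.
#'
#' @return Nested list with blocks `population`, `hazards`, `scheme`,
#'   `constraint`, `simulation`, `calibration`, `grid`.
#' @export
taviwait_defaults <- function() {
  list(
    population = list(n_patients = 50000L, mean_death12 = 0.036,
                      mean_hosp12 = 0.34, mean_urgent_given_hosp = 0.10,
                      dispersion_death = 0.05, dispersion_hosp = 0.5,
                      dispersion_urgent = 5, seed = 1L),
    hazards = list(shape_death = 1.5, shape_hosp = 1.5, mult_death = 1,
                   mult_hosp = 1, mult_urgent = 1, risk_horizon = 12),
    scheme = list(reference = TRUE, sizes = NULL, waits_prioritized = NULL,
                  classifier_outcome = "latent"),
    constraint = list(target_mean_wait = 12.5),
    simulation = list(n_replicates = 100L, patients_per_replicate = 50000L,
                      seed = 1L),
    calibration = list(referrals = 3030L, removed = 803L, tavis = 1330L,
                       deaths = 81L, hospitalized = 756L,
                       unscheduled = 202L, tolerance_pp = 0.1,
                       n_replicates = 20L, max_sweeps = 5L),
    grid = list(high_sizes = seq(0.05, 0.30, by = 0.05),
                medium_sizes = seq(0.05, 0.30, by = 0.05),
                high_waits = c(3, 4, 5), medium_increments = c(2, 4, 6),
                include_equal_thirds = TRUE, include_two_group = TRUE,
                max_low_wait = 16))
}

#' Read a JSON configuration file
#'
#' Unknown blocks or fields are an error (they are almost always typos);
#' missing ones fall back to [taviwait_defaults()].
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return Full configuration list, with attribute `"hash"` (a hex digest
#'   of the effective configuration, recorded in outputs).
#' @export
read_config <- function(path = NULL) {
  cfg <- taviwait_defaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config block(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (blk in names(user)) {
      badf <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(badf))
        stop(sprintf("unknown field(s) in config block '%s': %s", blk,
                     paste(badf, collapse = ", ")), call. = FALSE)
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    }
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Hash a configuration (31-polynomial over its canonical JSON, mod 2^31-1)
#' @param cfg Configuration list.
#' @return Hex string of 8 characters.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.population_from_config <- function(cfg) {
  do.call(population_params, cfg$population)
}

.hazards_from_config <- function(cfg) {
  do.call(hazard_params, cfg$hazards)
}

.scheme_from_config <- function(cfg) {
  s <- cfg$scheme
  if (isTRUE(s$reference)) return(reference_scheme())
  group_scheme(unlist(s$sizes), unlist(s$waits_prioritized),
               s$classifier_outcome)
}

.constraint_from_config <- function(cfg) {
  budget_constraint(cfg$constraint$target_mean_wait)
}
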