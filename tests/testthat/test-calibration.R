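test_that("registry counts turn into the printed percentage targets", {
  t <- registry_targets()
  expect_equal(round(t$mortality_target_pct, 1), 3.6)
  expect_equal(round(t$hospitalization_target_pct, 1), 33.9)
  expect_equal(round(t$urgent_share_target_pct, 1), 15.2)
  z <- registry_targets_from_counts(100, 0, 50, 0, 0, 0)
  expect_equal(z$mortality_target_pct, 0)
  expect_equal(z$urgent_share_target_pct, 0)
  d <- registry_targets_from_counts(1000, 100, 400, 45, 270, 80)
  expect_equal(d$mortality_target_pct, 5.0)
  expect_equal(d$hospitalization_target_pct, 30.0)
  expect_equal(d$urgent_share_target_pct, 20.0)
})

test_that("registry-count preconditions are enforced", {
  expect_error(registry_targets_from_counts(100, 100, 50, 1, 1, 1),
               "removed")
  expect_error(registry_targets_from_counts(100, 10, 50, 1, 1, 60),
               "unscheduled")
  expect_error(registry_targets_from_counts(100, 10, 0, 1, 1, 0), "zero")
  expect_error(registry_targets_from_counts(-1, 0, 5, 0, 0, 0),
               "non-negative")
  expect_error(calibration_targets(0, 30, 15), "0, 100")
})

test_that("each outcome is strictly increasing in its own multiplier", {
  spec <- scenario_spec(tiny_pop(2000L), reference_scheme(), hazard_params(),
                        n_replicates = 4L, patients_per_replicate = 2000L,
                        seed = 51L)
  prep <- taviwait:::.prepare_replicates(spec)
  run_with <- function(...) taviwait:::.run_prepared(prep, hazard_params(...))
  lo <- run_with(mult_death = 0.5, mult_hosp = 0.5, mult_urgent = 5)
  hi <- run_with(mult_death = 2, mult_hosp = 2, mult_urgent = 50)
  expect_lt(lo$mortality_pct, hi$mortality_pct)
  expect_lt(lo$hospitalization_pct, hi$hospitalization_pct)
  expect_lt(lo$urgent_pct, hi$urgent_pct)
})

test_that("calibrating to the model's own output returns multipliers near 1", {
  spec <- scenario_spec(tiny_pop(3000L), reference_scheme(), hazard_params(),
                        n_replicates = 6L, patients_per_replicate = 3000L,
                        seed = 61L)
  self <- run_scenario(spec)
  targets <- calibration_targets(self$mortality_pct,
                                 self$hospitalization_pct,
                                 self$urgent_pct, tolerance_pp = 0.1)
  res <- calibrate_reference(targets, spec)
  expect_true(res$converged)
  expect_length(res$trace, 1)  # one sweep suffices at the fixed point
  expect_equal(res$hazards$mult_death, 1, tolerance = 0.02)
  expect_equal(res$hazards$mult_hosp, 1, tolerance = 0.02)
  expect_equal(res$hazards$mult_urgent, 1, tolerance = 0.02)
})

test_that("raising the mortality target raises the fitted death multiplier", {
  spec <- scenario_spec(tiny_pop(3000L), reference_scheme(), hazard_params(),
                        n_replicates = 6L, patients_per_replicate = 3000L,
                        seed = 61L)
  self <- run_scenario(spec)
  t1 <- calibration_targets(self$mortality_pct, self$hospitalization_pct,
                            self$urgent_pct)
  t2 <- calibration_targets(2 * self$mortality_pct,
                            self$hospitalization_pct, self$urgent_pct)
  r1 <- calibrate_reference(t1, spec)
  r2 <- calibrate_reference(t2, spec)
  expect_gt(r2$hazards$mult_death, r1$hazards$mult_death)
  expect_lt(abs(r2$achieved[["death"]] - 2 * self$mortality_pct), 0.1)
})

test_that("calibration is reproducible and rejects non-reference schemes", {
  spec <- scenario_spec(tiny_pop(1500L), reference_scheme(), hazard_params(),
                        n_replicates = 3L, patients_per_replicate = 1500L,
                        seed = 71L)
  self <- run_scenario(spec)
  targets <- calibration_targets(self$mortality_pct,
                                 self$hospitalization_pct, self$urgent_pct)
  r1 <- calibrate_reference(targets, spec)
  r2 <- calibrate_reference(targets, spec)
  expect_identical(r1$hazards, r2$hazards)
  tier_spec <- spec
  tier_spec$scheme <- group_scheme(c(0.3, 0.7), 3)
  expect_error(calibrate_reference(targets, tier_spec), "reference")
})

test_that("an unreachable target reports a bound error", {
  spec <- scenario_spec(tiny_pop(1000L), reference_scheme(), hazard_params(),
                        n_replicates = 2L, patients_per_replicate = 1000L,
                        seed = 81L)
  targets <- calibration_targets(3.6, 99.9, 15.2)
  expect_error(calibrate_reference(targets, spec, mult_bounds = c(0.5, 2)),
               "unreachable")
})
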