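test_that("parameter validation names the offending field", {
  expect_error(population_params(n_patients = 0), "n_patients")
  expect_error(population_params(mean_death12 = 1.2), "mean_death12")
  expect_error(population_params(dispersion_hosp = -1), "dispersion_hosp")
  expect_error(population_params(mean_urgent_given_hosp = 1),
               "mean_urgent_given_hosp")
})

test_that("sampling is deterministic given the seed and leaves the caller's RNG alone", {
  p <- tiny_pop(200L, seed = 9L)
  set.seed(123)
  before <- .Random.seed
  c1 <- sample_cohort(p)
  expect_identical(.Random.seed, before)
  c2 <- sample_cohort(p)
  expect_identical(c1$profiles, c2$profiles)
  c3 <- sample_cohort(tiny_pop(200L, seed = 10L))
  expect_false(identical(c1$profiles$u_latent, c3$profiles$u_latent))
})

test_that("a degenerate zero mean yields all-zero risks on that margin", {
  coh <- sample_cohort(tiny_pop(100L, mean_death12 = 0))
  expect_true(all(coh$profiles$p_death12 == 0))
  expect_true(all(coh$profiles$p_hosp12 > 0))
})

test_that("empirical margin means match the configured means (law of large numbers)", {
  coh <- sample_cohort(population_params(n_patients = 100000L,
                                         mean_death12 = 0.05,
                                         dispersion_death = 3, seed = 5L))
  for (col in c("p_death12", "p_hosp12", "p_urgent_given_hosp")) {
    x <- coh$profiles[[col]]
    target <- switch(col, p_death12 = 0.05, p_hosp12 = 0.34,
                     p_urgent_given_hosp = 0.10)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target), 3 * se + 1e-12)
  }
})

test_that("margins are comonotone in the latent severity", {
  coh <- sample_cohort(tiny_pop(1000L))
  ord <- order(coh$profiles$u_latent)
  for (col in c("p_death12", "p_hosp12", "p_urgent_given_hosp"))
    expect_false(is.unsorted(coh$profiles[[col]][ord]))
})

test_that("with default dispersions the urgent margin is the most skewed", {
  coh <- sample_cohort(population_params(n_patients = 50000L, seed = 3L))
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  s <- vapply(coh$profiles[c("p_death12", "p_hosp12",
                             "p_urgent_given_hosp")], skew, numeric(1))
  expect_gt(s[["p_urgent_given_hosp"]], s[["p_death12"]])
  expect_gt(s[["p_urgent_given_hosp"]], s[["p_hosp12"]])
})

test_that("marginal_quantile is the margin's inverse CDF", {
  p <- population_params()
  # symmetric margin: equal Beta shapes at mean 1/2, median = mean
  sym <- population_params(mean_hosp12 = 0.5)
  expect_equal(marginal_quantile(sym, "hosp", 0.5), 0.5)
  # strict monotonicity
  expect_gt(marginal_quantile(p, "death", 0.95),
            marginal_quantile(p, "death", 0.90))
  # brute-force bisection on the CDF, defaults, u = 0.90
  for (oc in c("death", "hosp", "urgent")) {
    m <- switch(oc, death = c(0.036, 0.05), hosp = c(0.34, 0.5),
                urgent = c(0.10, 5))
    s <- 1 / m[2]
    oracle <- bisect_quantile(function(x) pbeta(x, m[1] * s, (1 - m[1]) * s),
                              0.90)
    expect_equal(marginal_quantile(p, oc, 0.90), oracle, tolerance = 1e-10)
  }
  expect_error(marginal_quantile(p, "death", 0), "\\(0, 1\\)")
  expect_error(marginal_quantile(p, "death", 1), "\\(0, 1\\)")
})

test_that("risk_percentile_threshold matches a sort-based oracle", {
  coh <- sample_cohort(tiny_pop(997L, seed = 8L))
  for (f in c(0.05, 0.10, 0.30, 0.5, 0.9)) {
    expect_equal(risk_percentile_threshold(coh, "death", f),
                 brute_threshold(coh$profiles$p_death12, f))
    expect_equal(risk_percentile_threshold(coh, "urgent", f),
                 brute_threshold(coh$profiles$p_urgent_given_hosp, f))
  }
  # top 10% -> 90th percentile; at most n * f patients strictly above
  thr <- risk_percentile_threshold(coh, "hosp", 0.10)
  expect_lte(sum(coh$profiles$p_hosp12 > thr), ceiling(997 * 0.10))
})

test_that("degenerate all-equal risks return the common value", {
  coh <- sample_cohort(tiny_pop(50L))
  coh$profiles$p_death12 <- rep(0.2, 50)
  for (f in c(0.1, 0.5, 0.9))
    expect_equal(risk_percentile_threshold(coh, "death", f), 0.2)
  empty <- coh; empty$profiles <- coh$profiles[0, ]
  expect_error(risk_percentile_threshold(empty, "death", 0.1), "empty")
})

test_that("cohort CSV round-trips at full precision", {
  coh <- sample_cohort(tiny_pop(40L, seed = 2L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(back$profiles$p_death12, coh$profiles$p_death12,
               tolerance = 1e-15)
  expect_equal(back$profiles$u_latent, coh$profiles$u_latent,
               tolerance = 1e-15)
  # missing column is named in the error
  bad <- read.csv(f)
  bad$p_hosp12 <- NULL
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_cohort_csv(f), "p_hosp12")
})
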