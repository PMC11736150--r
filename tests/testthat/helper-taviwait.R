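# Shared fixtures, built in code at test time.

tiny_pop <- function(n = 500L, seed = 42L, ...) {
  population_params(n_patients = n, seed = seed, ...)
}

registry_targets <- function(tolerance_pp = 0.1) {
  registry_targets_from_counts(3030, 803, 1330, 81, 756, 202,
                               tolerance_pp = tolerance_pp)
}

# brute-force empirical quantile by full sort (nearest-rank, ceiling)
brute_threshold <- function(x, top_fraction) {
  sort(x)[min(max(ceiling(length(x) * (1 - top_fraction)), 1), length(x))]
}

# bisection inversion of a CDF, independent of qbeta
bisect_quantile <- function(cdf, u, lower = 0, upper = 1, tol = 1e-12) {
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (cdf(mid) < u) lower <- mid else upper <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}
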