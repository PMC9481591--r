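# Shared fixtures and independent reference implementations.

# Independent restricted-cubic-spline implementation straight from the
# published truncated-power formula, scalar loops only: the oracle for the
# vectorized basis in the package.
rcs_basis_reference <- function(ages, knots, center_age) {
  k <- length(knots)
  out <- matrix(0, length(ages), k - 1)
  for (i in seq_along(ages)) {
    x <- ages[i]
    out[i, 1] <- x - center_age
    for (j in 1:(k - 2)) {
      tp <- function(u) if (u > 0) u^3 else 0
      out[i, j + 1] <- (tp(x - knots[j]) -
        tp(x - knots[k - 1]) * (knots[k] - knots[j]) /
          (knots[k] - knots[k - 1]) +
        tp(x - knots[k]) * (knots[k - 1] - knots[j]) /
          (knots[k] - knots[k - 1])) / (knots[k] - knots[1])^2
    }
  }
  out
}

# Small single-sex synthetic count table.
small_counts <- function(n_areas = 60, years = 2011, seed = 1,
                         hazard = test_hazard(), sex = "male") {
  tr <- generate_tracts(n_areas, n_provinces = 3, years = years, seed = seed)
  tr <- tr[tr$sex == sex, ]
  simulate_counts(tr, hazard, seed = seed + 1000)
}

test_hazard <- function(frailty_sd = 0.1) {
  hazard_spec(makeham_c = 2e-4, gompertz_b = 3e-5, gompertz_theta = 0.1,
              quintile_log_effects = c(0, 0.1, 0.2, 0.3, 0.4),
              frailty_sd = frailty_sd)
}

# One moderately sized fitted model, computed lazily and reused across test
# files to keep the suite fast.
.fixture_cache <- new.env(parent = emptyenv())
fixture_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    cc <- small_counts(n_areas = 150, years = 2011:2012, seed = 42)
    .fixture_cache$counts <- cc
    .fixture_cache$fit <- fit_poisson_mixed(build_design(cc))
  }
  list(fit = .fixture_cache$fit, counts = .fixture_cache$counts)
}
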