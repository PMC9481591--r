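test_that("delta-method intervals collapse and bracket correctly", {
  fx <- fixture_fit()
  fit <- fx$fit
  pr <- predict_rates(fit, c(2.5, 40, 90), "Q2")
  expect_true(all(pr$ci_low > 0))
  expect_true(all(pr$ci_low <= pr$rate & pr$rate <= pr$ci_high))
  expect_true(all(pr$rate > 0))

  # zero covariance: interval degenerates to the point estimate
  fit0 <- fit
  fit0$vcov_beta <- fit$vcov_beta * 0
  pr0 <- predict_rates(fit0, c(10, 50, 90), "Q4")
  expect_equal(pr0$ci_low, pr0$rate)
  expect_equal(pr0$ci_high, pr0$rate)
  expect_equal(pr0$se_log_rate, rep(0, 3))

  expect_error(predict_rates(fit, 150, "Q1"), "110")
  expect_error(predict_rates(fit, 50, "Q1", area_id = "nope"),
               "unknown area")
  # area prediction shifts the rate by exp(u)
  a <- names(fit$area_intercepts)[1]
  pa <- predict_rates(fit, 50, fit$area_quintile[[a]], area_id = a)
  pq <- predict_rates(fit, 50, fit$area_quintile[[a]])
  expect_equal(pa$rate / pq$rate, exp(fit$area_intercepts[[a]]),
               tolerance = 1e-10)
})

test_that("a saturated one-cell model reproduces the observed rate", {
  d <- structure(list(X = matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")),
                      y = 5, offset = log(1000),
                      area = factor("A1"),
                      rows = data.frame(age = 50, quintile = "Q1"),
                      spec = spline_spec(c(10, 40, 70)),
                      open_band_age = 90), class = "model_design")
  fit <- fit_poisson_mixed(d, fix_sigma = 0)
  expect_equal(exp(unname(fit$beta[1])), 5 / 1000, tolerance = 1e-8)
})

test_that("predicted log rate is linear in age beyond the boundary knots", {
  fx <- fixture_fit()
  for (q in c("Q1", "Q5")) {
    lr <- function(x) log(predict_rates(fx$fit, x, q)$rate)
    for (x in c(95, 105)) {  # beyond the last knot at 82
      d2 <- lr(x + 1) - 2 * lr(x) + lr(x - 1)
      expect_lt(abs(d2), 1e-8)
    }
  }
})

test_that("observed and fitted rates agree when refit on fitted counts", {
  # large populations make the integer rounding of fitted counts negligible
  tr <- generate_tracts(25, n_provinces = 2, mean_pop = 60000, seed = 17)
  tr <- tr[tr$sex == "male", ]
  cc <- simulate_counts(tr, test_hazard(frailty_sd = 0), seed = 18)
  fit <- fit_poisson_mixed(build_design(cc), fix_sigma = 0)
  gof <- goodness_of_fit(fit, cc)
  expect_equal(nrow(gof$table), 18 * 5)

  age <- ifelse(is.na(cc$age_upper), 90, (cc$age_lower + cc$age_upper) / 2)
  X <- deplife:::fixed_matrix(age, cc$quintile, fit$spec)
  refit_data <- cc
  refit_data$deaths <- as.integer(round(cc$population *
                                          exp(drop(X %*% fit$beta))))
  refit <- fit_poisson_mixed(build_design(refit_data), fix_sigma = 0)
  gof2 <- goodness_of_fit(refit, refit_data)
  expect_lt(gof2$mae, 2e-4)
})

test_that("dropping the quintile-age interaction worsens adult fit", {
  cc <- small_counts(n_areas = 150, years = 2011:2012, seed = 19,
                     hazard = hazard_spec(
                       quintile_log_effects = c(0, 0.15, 0.3, 0.45, 0.6),
                       frailty_sd = 0.05))
  d_full <- build_design(cc)
  fit_full <- fit_poisson_mixed(d_full)
  d_red <- d_full
  keep <- 1:(1 + 7 + 4)          # intercept + spline + quintile main effects
  d_red$X <- d_full$X[, keep]
  fit_red <- fit_poisson_mixed(d_red)
  # pooled observed/fitted MAE over ages > 20, computed per design
  mae_adult <- function(fit, X) {
    pred <- exp(drop(X %*% fit$beta) + fit$area_intercepts[cc$area_id])
    keep <- !is.na(cc$age_upper) & (cc$age_lower + cc$age_upper) / 2 > 20 |
      is.na(cc$age_upper)
    key <- list(quintile = cc$quintile[keep], age = cc$age_lower[keep])
    od <- aggregate(list(d = cc$deaths[keep]), key, sum)
    op <- aggregate(list(py = cc$population[keep]), key, sum)
    fp <- aggregate(list(wp = (pred * cc$population)[keep]), key, sum)
    mean(abs(od$d / op$py - fp$wp / op$py))
  }
  expect_lt(mae_adult(fit_full, d_full$X), mae_adult(fit_red, d_red$X))
})

test_that("fitted models survive a JSON round trip", {
  fx <- fixture_fit()
  path <- tempfile(fileext = ".json")
  write_model(fx$fit, path)
  back <- read_model(path)
  pr1 <- predict_rates(fx$fit, c(5, 50, 95), "Q3")
  pr2 <- predict_rates(back, c(5, 50, 95), "Q3")
  expect_equal(pr2$rate, pr1$rate, tolerance = 1e-8)
  expect_equal(pr2$ci_low, pr1$ci_low, tolerance = 1e-8)
  expect_equal(back$sigma_u, fx$fit$sigma_u)
  a <- names(fx$fit$area_intercepts)[3]
  expect_equal(predict_rates(back, 70, back$area_quintile[[a]], area_id = a)$rate,
               predict_rates(fx$fit, 70, fx$fit$area_quintile[[a]], area_id = a)$rate)
})

test_that("knot selection honours trivial contracts", {
  cc <- small_counts(n_areas = 30, seed = 21)
  one <- select_knots(cc, list(c(5, 40, 80)), n_folds = 3, seed = 1)
  expect_equal(one$spec$knots, c(5, 40, 80))

  two <- select_knots(cc, list(c(5, 40, 80), c(5, 40, 80)), n_folds = 3,
                      seed = 1)
  expect_equal(two$cv$cv_mae[1], two$cv$cv_mae[2])
  # exact tie broken toward the first (identical) candidate
  expect_equal(two$spec$knots, c(5, 40, 80))

  rerun <- select_knots(cc, list(c(5, 40, 80), c(5, 40, 80)), n_folds = 3,
                        seed = 1)
  expect_identical(two$cv, rerun$cv)
  expect_error(select_knots(cc, list()), "at least one")
})
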