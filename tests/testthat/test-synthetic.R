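test_that("quintile assignment is balanced and rank-based", {
  tr <- generate_tracts(100, seed = 1)
  per_area <- unique(tr[, c("area_id", "quintile")])
  expect_equal(unname(table(per_area$quintile)), rep(20L, 5),
               ignore_attr = TRUE)

  tr7 <- generate_tracts(7, seed = 1)
  sizes <- sort(as.integer(table(unique(tr7[, c("area_id", "quintile")])$quintile)))
  expect_equal(sizes, c(1L, 1L, 1L, 2L, 2L))

  for (n in c(5, 13, 101, 250)) {
    sizes <- table(unique(generate_tracts(n, seed = 3)[, c("area_id", "quintile")])$quintile)
    expect_true(max(sizes) - min(sizes) <= 1)
  }
  expect_error(generate_tracts(4), "quintile")
})

test_that("generation is a pure function of arguments and seed", {
  a <- generate_tracts(30, seed = 9)
  b <- generate_tracts(30, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_tracts(30, seed = 10)))
  # no global RNG side effects
  set.seed(123); before <- .Random.seed
  invisible(generate_tracts(10, seed = 5))
  expect_identical(before, .Random.seed)
  expect_true(all(a$population > 0))
})

test_that("true_rate matches its closed form", {
  hz <- hazard_spec(makeham_c = 0, gompertz_b = 1e-4, gompertz_theta = 0.09,
                    age_profile = "linear")
  expect_equal(true_rate(hz, 0, "Q1"), 1e-4)
  expect_equal(true_rate(hz, 80, "Q1"), 1e-4 * exp(7.2))

  hz5 <- hazard_spec(makeham_c = 0, gompertz_b = 1e-4, gompertz_theta = 0.09,
                     quintile_log_effects = c(0, 0, 0, 0, 0.18),
                     age_profile = "linear")
  for (a in c(0, 10, 42.5, 90))
    expect_equal(true_rate(hz5, a, "Q5"), exp(0.18) * true_rate(hz5, a, "Q1"))
})

test_that("rates increase across quintiles at every age for ordered effects", {
  for (profile in c("bump", "linear")) {
    hz <- hazard_spec(quintile_log_effects = c(0, 0.1, 0.2, 0.3, 0.4),
                      age_profile = profile)
    for (a in c(0, 1, 15, 40, 70, 95, 110)) {
      r <- vapply(1:5, function(k) true_rate(hz, a, k), numeric(1))
      expect_true(all(diff(r) > 0))
    }
  }
})

test_that("life-expectancy oracle: exponential mean, grid convergence, ODE", {
  hz <- hazard_spec(makeham_c = 0.0125, gompertz_b = 1e-12,
                    gompertz_theta = 0, age_profile = "linear")
  expect_equal(true_life_expectancy(hz, "Q1"), 80, tolerance = 1e-3)
  # from_age independence under constant hazard
  expect_equal(true_life_expectancy(hz, "Q1", from_age = 40), 80,
               tolerance = 1e-3)

  gomp <- hazard_spec(makeham_c = 0, gompertz_b = 1e-4, gompertz_theta = 0.1,
                      age_profile = "linear")
  e1 <- true_life_expectancy(gomp, "Q1", step = 0.01)
  e2 <- true_life_expectancy(gomp, "Q1", step = 0.005)
  expect_lt(abs(e1 - e2), 1e-4)

  # independent integrator: survival ODE S' = -h S, LE = integral of S
  ode <- deSolve::ode(y = c(S = 1, I = 0), times = seq(0, 120, 0.1),
                      func = function(t, y, p) {
                        h <- 1e-4 * exp(0.1 * t)
                        list(c(-h * y[["S"]], y[["S"]]))
                      })
  expect_lt(abs(e1 - ode[nrow(ode), "I"]), 1e-3)
})

test_that("simulated counts have the right Poisson mean structure", {
  # negligible hazard implies zero deaths
  null_hz <- hazard_spec(makeham_c = 0, gompertz_b = 1e-30,
                         gompertz_theta = 0, frailty_sd = 0,
                         age_profile = "linear")
  tr <- generate_tracts(6, seed = 2)
  expect_true(all(simulate_counts(tr, null_hz, seed = 1)$deaths == 0))

  # Monte-Carlo mean of one cell vs person-years x band rate
  hz <- test_hazard(frailty_sd = 0)
  frame <- data.frame(area_id = "A0001", province_id = "P01",
                      quintile = "Q3", sex = "male", year = 2011,
                      age_lower = 70, age_upper = 75, population = 5000)
  draws <- vapply(1:2000, function(s)
    simulate_counts(frame, hz, seed = s)$deaths, numeric(1))
  expected <- 5000 * band_average_rate(hz, "Q3", 70, 75)
  se <- sqrt(expected / 2000)
  expect_lt(abs(mean(draws) - expected), 3 * se)

  # doubling person-years doubles expected deaths
  frame2 <- frame; frame2$population <- 2 * frame$population
  d1 <- mean(vapply(1:400, function(s)
    simulate_counts(frame, hz, seed = s)$deaths, numeric(1)))
  d2 <- mean(vapply(1:400, function(s)
    simulate_counts(frame2, hz, seed = s)$deaths, numeric(1)))
  expect_equal(d2 / d1, 2, tolerance = 0.1)
})

test_that("count tables round-trip through the CSV schema", {
  cc <- small_counts(n_areas = 8, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_counts(cc, path)
  back <- read_counts(path)
  expect_equal(back$deaths, cc$deaths)
  expect_equal(back$population, cc$population)
  expect_true(all(is.na(back$age_upper[back$age_lower == 85])))
  # header is the documented schema
  expect_identical(names(back),
                   c("area_id", "province_id", "quintile", "sex", "year",
                     "age_lower", "age_upper", "deaths", "population"))
})

test_that("hazard and gap calibration hit their targets", {
  hz <- calibrate_quintile_gap(test_hazard(), gap = 3)
  g <- true_life_expectancy(hz, "Q1") - true_life_expectancy(hz, "Q5")
  expect_equal(g, 3, tolerance = 0.01)
  expect_error(hazard_spec(quintile_log_effects = c(0.1, 0, 0, 0, 0)),
               "Q1")
  expect_error(hazard_spec(gompertz_b = 0), "gompertz_b")
})
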