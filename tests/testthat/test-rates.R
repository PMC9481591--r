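test_that("crude rates reproduce published national values per 1,000", {
  # national aggregate counts shipped with the package
  tab <- national_quintile_counts()
  cell <- function(sx, yr, q) tab[tab$sex == sx & tab$year == yr &
                                    tab$quintile == q, ]
  checks <- list(
    list(cell("male", 2012, "Q3"), 8.92),
    list(cell("female", 2013, "Q5"), 9.34),
    list(cell("male", 2011, "Q2"), 7.77),
    list(cell("female", 2011, "Q1"), 6.77))
  for (ch in checks) {
    est <- crude_rate(ch[[1]]$deaths, ch[[1]]$population, scale = 1000)
    expect_equal(round(est$rate, 2), ch[[2]])
  }
})

test_that("crude-rate intervals behave like exact Poisson limits", {
  z <- crude_rate(0, 1000)
  expect_equal(z$rate, 0)
  expect_equal(z$ci_low, 0)
  expect_gt(z$ci_high, 0)
  expect_error(crude_rate(5, 0), "person_years")
  expect_error(crude_rate(-1, 10), "deaths")

  # interval brackets the estimate; width shrinks with person-years at a
  # fixed rate
  widths <- vapply(c(1e3, 1e4, 1e5, 1e6), function(py) {
    est <- crude_rate(0.01 * py, py)
    expect_lte(est$ci_low, est$rate)
    expect_gte(est$ci_high, est$rate)
    est$ci_high - est$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # Garwood limits against the chi-square definition
  est <- crude_rate(42, 1e4, scale = 1, level = 0.95)
  expect_equal(est$ci_low, qchisq(0.025, 84) / 2 / 1e4)
  expect_equal(est$ci_high, qchisq(0.975, 86) / 2 / 1e4)
})

test_that("stratified rates pool deaths and person-years before dividing", {
  one <- data.frame(quintile = "Q1", deaths = 7, population = 1234)
  s <- stratum_rates(one, by = "quintile")
  expect_equal(s$rate, crude_rate(7, 1234)$rate)

  # two strata with equal rates pool to the same rate
  two <- data.frame(quintile = c("Q1", "Q1"), deaths = c(10, 30),
                    population = c(1000, 3000))
  expect_equal(stratum_rates(two, by = "quintile")$rate,
               crude_rate(10, 1000)$rate)

  three <- data.frame(sex = c("m", "m", "f"), deaths = c(3, 5, 11),
                      population = c(100, 200, 400))
  s3 <- stratum_rates(three, by = "sex", scale = 1)
  expect_equal(s3$deaths[s3$sex == "m"], 8)
  expect_equal(s3$rate[s3$sex == "m"], 8 / 300)
  expect_equal(s3$rate[s3$sex == "f"], 11 / 400)

  # aggregation consistency: recombining a partition reproduces the total
  cc <- small_counts(n_areas = 10, seed = 6)
  parts <- stratum_rates(cc, by = "quintile")
  total <- crude_rate(sum(cc$deaths), sum(cc$population))
  expect_equal(sum(parts$deaths) / sum(parts$person_years) * 1000,
               total$rate)
  expect_error(stratum_rates(cc, by = "nope"), "not present")
})

test_that("indirect SMR satisfies its identities and worked example", {
  ref <- data.frame(age_lower = c(0, 5), deaths = c(10, 100),
                    population = c(1000, 1000))
  # reference against itself
  expect_equal(smr_indirect(ref, ref)$smr, 1)

  # uniform doubling of rates
  idx <- ref; idx$deaths <- idx$deaths * 2
  expect_equal(smr_indirect(idx, ref)$smr, 2)

  # two-band worked example: rates 0.01 and 0.10, person-years 1000/100,
  # observed 25 deaths -> expected 20, SMR 1.25
  refr <- data.frame(age_lower = c(0, 5), rate = c(0.01, 0.10))
  idx2 <- data.frame(age_lower = c(0, 5), deaths = c(15, 10),
                     population = c(1000, 100))
  s <- smr_indirect(idx2, refr)
  expect_equal(s$expected, 20)
  expect_equal(s$smr, 1.25)
  expect_lt(s$ci_low, 1.25)
  expect_gt(s$ci_high, 1.25)

  # missing reference band names the band
  expect_error(smr_indirect(data.frame(age_lower = 10, deaths = 1,
                                       population = 10), refr), "10")
})

test_that("calendar trend test recovers flat and doubling rates", {
  flat <- data.frame(year = 2011:2015, deaths = rep(500, 5),
                     person_years = rep(1e5, 5))
  t1 <- trend_test(flat)
  expect_equal(t1$slope, 0, tolerance = 1e-8)
  expect_gt(t1$p_value, 0.99)

  doubling <- data.frame(year = 2011:2015,
                         deaths = round(1000 * 2^(0:4)),
                         person_years = rep(1e7, 5))
  t2 <- trend_test(doubling)
  expect_equal(t2$slope, log(2), tolerance = 0.01)
  expect_lt(t2$p_value, 1e-3)

  expect_error(trend_test(flat[1:2, ]), "3 calendar years")
  expect_error(trend_test(data.frame(year = 1:3, deaths = 0,
                                     person_years = 10)), "zero")
})
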