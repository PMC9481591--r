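#' Crude mortality rate with Poisson confidence interval
#'
#' Point estimate `deaths / person_years * scale` with a 95% (or other
#' level) confidence interval. The default interval is the exact Poisson
#' (Garwood) chi-square interval on the death count divided by person-years;
#' a normal approximation is available for comparison with published tables.
#'
#' @param deaths Death count(s), non-negative integers. Vectorized.
#' @param person_years Person-years at risk, > 0.
#' @param scale Display multiplier (default 1000: rate per 1,000
#'   person-years).
#' @param level Confidence level (default 0.95).
#' @param method `"exact"` (Garwood) or `"normal"`.
#' @return Data frame with columns `rate`, `ci_low`, `ci_high`, `n_deaths`,
#'   `person_years` (rate and CI on the display scale).
#' @examples
#' crude_rate(42394, 4750182, scale = 1000)  # 8.92 per 1,000
#' @export
crude_rate <- function(deaths, person_years, scale = 1000, level = 0.95,
                       method = c("exact", "normal")) {
  method <- match.arg(method)
  if (any(person_years <= 0)) stop("person_years must be strictly positive")
  if (any(deaths < 0)) stop("deaths must be non-negative")
  n <- max(length(deaths), length(person_years))
  deaths <- rep_len(deaths, n)
  person_years <- rep_len(person_years, n)
  alpha <- 1 - level
  if (method == "exact") {
    lo <- ifelse(deaths == 0, 0, stats::qchisq(alpha / 2, 2 * deaths) / 2)
    hi <- stats::qchisq(1 - alpha / 2, 2 * deaths + 2) / 2
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    lo <- pmax(0, deaths - z * sqrt(deaths))
    hi <- deaths + z * sqrt(deaths)
  }
  data.frame(rate = deaths / person_years * scale,
             ci_low = lo / person_years * scale,
             ci_high = hi / person_years * scale,
             n_deaths = deaths, person_years = person_years)
}

#' Stratified crude rates
#'
#' Sums deaths and person-years within each stratum before dividing (rates
#' are never averaged), then applies [crude_rate()]. Strata whose summed
#' person-years are zero are omitted with a warning.
#'
#' @param table Abridged count table (needs `deaths` and `population`
#'   columns plus the stratification keys).
#' @param by Character vector of column names to stratify by.
#' @inheritParams crude_rate
#' @return Data frame: one row per stratum with the keys, `deaths`,
#'   `person_years`, `rate`, `ci_low`, `ci_high`.
#' @export
stratum_rates <- function(table, by, scale = 1000, level = 0.95,
                          method = c("exact", "normal")) {
  missing_keys <- setdiff(by, names(table))
  if (length(missing_keys))
    stop("stratification keys not present: ",
         paste(missing_keys, collapse = ", "))
  agg <- stats::aggregate(table[, c("deaths", "population")],
                          by = table[, by, drop = FALSE], FUN = sum)
  empty <- agg$population <= 0
  if (any(empty)) {
    warning(sum(empty), " stratum/strata with no person-years omitted")
    agg <- agg[!empty, , drop = FALSE]
  }
  est <- crude_rate(agg$deaths, agg$population, scale = scale, level = level,
                    method = method)
  out <- cbind(agg[, by, drop = FALSE],
               data.frame(deaths = agg$deaths, person_years = agg$population,
                          rate = est$rate, ci_low = est$ci_low,
                          ci_high = est$ci_high))
  rownames(out) <- NULL
  out
}

#' Standardized mortality ratio, indirect method
#'
#' Expected deaths are the reference stratum's age-band-specific rates
#' applied to the index stratum's person-years; the SMR is observed over
#' expected, with a 95% confidence interval from Byar's approximation on the
#' observed count.
#'
#' @param index Count table rows of the index stratum (columns `age_lower`,
#'   `deaths`, `population`; multiple rows per band allowed).
#' @param reference Either a count table of the reference stratum (same
#'   columns, aggregated internally) or a data frame with `age_lower` and
#'   `rate` (per person-year).
#' @param level Confidence level (default 0.95).
#' @param reference_label Label stored in the result.
#' @return List of class `smr_estimate`: `observed`, `expected`, `smr`,
#'   `ci_low`, `ci_high`, `reference_label`.
#' @export
smr_indirect <- function(index, reference, level = 0.95,
                         reference_label = "reference") {
  stopifnot(all(c("age_lower", "deaths", "population") %in% names(index)))
  if ("rate" %in% names(reference)) {
    ref <- reference[, c("age_lower", "rate")]
  } else {
    agg <- stats::aggregate(reference[, c("deaths", "population")],
                            by = reference[, "age_lower", drop = FALSE],
                            FUN = sum)
    ref <- data.frame(age_lower = agg$age_lower,
                      rate = agg$deaths / agg$population)
  }
  idx <- stats::aggregate(index[, c("deaths", "population")],
                          by = index[, "age_lower", drop = FALSE], FUN = sum)
  m <- match(idx$age_lower, ref$age_lower)
  if (anyNA(m))
    stop("reference has no rate for age band(s) starting at: ",
         paste(idx$age_lower[is.na(m)], collapse = ", "))
  expected <- sum(ref$rate[m] * idx$population)
  observed <- sum(idx$deaths)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci_low <- if (observed == 0) 0 else
    observed * (1 - 1 / (9 * observed) - z / (3 * sqrt(observed)))^3 / expected
  op1 <- observed + 1
  ci_high <- op1 * (1 - 1 / (9 * op1) + z / (3 * sqrt(op1)))^3 / expected
  structure(list(observed = observed, expected = expected,
                 smr = observed / expected, ci_low = ci_low,
                 ci_high = ci_high, reference_label = reference_label),
            class = "smr_estimate")
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("SMR (indirect, ref = %s): %.3f (%.3f-%.3f); O = %g, E = %.1f\n",
              x$reference_label, x$smr, x$ci_low, x$ci_high,
              x$observed, x$expected))
  invisible(x)
}

#' Poisson log-linear trend test over calendar years
#'
#' Fits `deaths ~ year` with a log person-years offset by iteratively
#' reweighted least squares (a Poisson GLM) and returns the Wald test of the
#' calendar-year slope.
#'
#' @param yearly Data frame with columns `year`, `deaths`, `person_years`
#'   (one row per year, or multiple rows aggregated internally), >= 3
#'   distinct years.
#' @return List: `slope` (log-rate change per year), `se`, `p_value`, and
#'   the fitted `glm` object.
#' @export
trend_test <- function(yearly) {
  stopifnot(all(c("year", "deaths", "person_years") %in% names(yearly)))
  agg <- stats::aggregate(yearly[, c("deaths", "person_years")],
                          by = yearly[, "year", drop = FALSE], FUN = sum)
  if (nrow(agg) < 3) stop("trend test needs at least 3 calendar years")
  if (all(agg$deaths == 0)) stop("all death counts are zero")
  fit <- stats::glm(deaths ~ year + offset(log(person_years)),
                    family = stats::poisson(), data = agg)
  sm <- summary(fit)$coefficients
  list(slope = sm["year", "Estimate"], se = sm["year", "Std. Error"],
       p_value = sm["year", "Pr(>|z|)"], model = fit)
}
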