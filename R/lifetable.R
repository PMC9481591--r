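#' Build a complete (single-year) life table from central death rates
#'
#' Standard period life-table construction on a single-year age grid
#' 0, 1, ..., `open age`. For closed intervals the death probability is
#' `q = m / (1 + (1 - a) m)` (capped at 1), with separation factor
#' `a(0) = a0` (low-mortality infant convention, default 0.1) and `a = ax`
#' (default 0.5) at other ages. The open interval has `q = 1` and
#' `L = l / m`. Survivors `l` start at the radix; `d`, `L`, `T`, `e` follow
#' the standard recursion.
#'
#' @param m Central death rates (per person-year) for ages `0, 1, ...`,
#'   the last element being the open interval. All must be positive and
#'   finite.
#' @param a0 Separation factor of age 0 (default 0.1).
#' @param ax Separation factor of other closed single-year ages
#'   (default 0.5).
#' @param radix Survivors at age 0 (default 100000).
#' @param ages Optional explicit ages (default `0:(length(m) - 1)`); must be
#'   contiguous single years from 0.
#' @return Data frame of class `life_table` with columns `age`, `m`, `a`,
#'   `q`, `l`, `d`, `L`, `T`, `e`.
#' @examples
#' lt <- rates_to_lifetable(rep(0.0125, 111))
#' life_expectancy_at(lt, 0)  # close to 1/0.0125 = 80 years
#' @export
rates_to_lifetable <- function(m, a0 = 0.1, ax = 0.5, radix = 1e5,
                               ages = seq_along(m) - 1) {
  if (!identical(as.numeric(ages), as.numeric(seq_along(m) - 1)))
    stop("ages must be contiguous single years starting at 0")
  bad <- which(!is.finite(m) | m <= 0)
  if (length(bad))
    stop("non-positive or non-finite rate at age ",
         paste(ages[bad], collapse = ", "))
  n <- length(m)
  a <- c(a0, rep(ax, n - 2), NA)
  q <- pmin(1, m / (1 + (1 - a) * m))
  q[n] <- 1
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  i <- seq_len(n - 1)
  L <- numeric(n)
  L[i] <- l[i] - (1 - a[i]) * d[i]   # = l(x+1) + a d
  L[n] <- l[n] / m[n]
  TT <- rev(cumsum(rev(L)))
  e <- TT / l
  structure(data.frame(age = ages, m = m, a = a, q = q, l = l, d = d,
                       L = L, T = TT, e = e),
            class = c("life_table", "data.frame"))
}

#' Build an abridged (5-year band) life table from band rates
#'
#' Companion constructor on the abridged grid 0-4, 5-9, ..., open band:
#' `q = n m / (1 + (n - a) m)` with band width `n = 5` and separation factor
#' `a` in years (default `n/2`); open band as in [rates_to_lifetable()].
#' Provided for comparison with the single-year construction.
#'
#' @param m Band central death rates, last element the open band.
#' @param age_lower Band lower bounds (default `0, 5, ...`).
#' @param a_band Separation factor in years within closed bands
#'   (default 2.5).
#' @param radix Survivors at age 0.
#' @return Data frame of class `life_table` (column `age` holds the band
#'   lower bound).
#' @export
rates_to_lifetable_abridged <- function(m, age_lower = seq(0, by = 5,
                                          length.out = length(m)),
                                        a_band = 2.5, radix = 1e5) {
  bad <- which(!is.finite(m) | m <= 0)
  if (length(bad))
    stop("non-positive or non-finite rate at band starting ",
         paste(age_lower[bad], collapse = ", "))
  n <- length(m)
  width <- diff(age_lower)
  q <- c(pmin(1, width * m[-n] / (1 + (width - a_band) * m[-n])), 1)
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- c(width * l[-1] + a_band * d[-n], l[n] / m[n])
  TT <- rev(cumsum(rev(L)))
  e <- TT / l
  structure(data.frame(age = age_lower, m = m, q = q, l = l, d = d,
                       L = L, T = TT, e = e),
            class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat(sprintf("Life table: %d intervals, open at age %g; e(0) = %.2f years\n",
              nrow(x), x$age[nrow(x)], x$e[1]))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = digits)
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Remaining life expectancy at an exact age
#'
#' @param lt A `life_table`.
#' @param age Exact age on the table's grid.
#' @return List of class `le_result`: `at_age`, `le` (years).
#' @export
life_expectancy_at <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(age, lt$age)
  if (is.na(i)) {
    if (age > max(lt$age)) stop("age is beyond the open interval")
    stop("age ", age, " is not on the life-table grid")
  }
  structure(list(at_age = age, le = lt$e[i]), class = "le_result")
}

#' @export
print.le_result <- function(x, ...) {
  cat(sprintf("Remaining life expectancy at age %g: %.2f years\n",
              x$at_age, x$le))
  invisible(x)
}

# Single-year rate schedule for one quintile from a fitted model: closed
# intervals 0..(open_age-1) predicted at their midpoints, open interval at
# open_age. re_mode "zero" predicts the median area (random intercept 0);
# "average" multiplies rates by exp(sigma_u^2 / 2), the mean over the tract
# frailty distribution.
model_rate_schedule <- function(model, quintile, open_age = 100,
                                re_mode = c("zero", "average"),
                                area_id = NULL) {
  re_mode <- match.arg(re_mode)
  ages <- c(seq_len(open_age) - 0.5, open_age)
  pr <- predict_rates(model, ages, quintile, area_id = area_id)
  m <- pr$rate
  if (re_mode == "average") m <- m * exp(model$sigma_u^2 / 2)
  # weakly identified cells (e.g. childhood ages with no observed deaths in
  # a quintile) can drive the predicted rate to numerical zero; floor at a
  # demographically negligible hazard so the table stays well defined
  pmax(m, 1e-12)
}

#' Life tables and life expectancy by deprivation quintile
#'
#' Predicts single-year mortality rates for ages 0..`open_age - 1` (at the
#' interval midpoints) plus the open interval from the fitted model for each
#' quintile, builds a complete life table per quintile, and returns life
#' expectancy at birth and at age 75. The random intercept is set to 0
#' (median tract) under `re_mode = "zero"`, or averaged over the tract
#' frailty distribution under `re_mode = "average"`.
#'
#' @param model A converged [fit_poisson_mixed()] fit.
#' @param sex Optional label carried into the results.
#' @param open_age Open interval age of the constructed tables
#'   (default 100; predictions past the last knot extrapolate the spline's
#'   linear tail).
#' @param re_mode `"zero"` or `"average"`, see above.
#' @param le_ages Ages at which to report life expectancy
#'   (default `c(0, 75)`).
#' @param a0,ax Separation factors passed to [rates_to_lifetable()].
#' @return List: `tables` (named list of 5 `life_table`s) and `le` (data
#'   frame: sex, stratum, at_age, le).
#' @export
quintile_lifetables <- function(model, sex = NA_character_, open_age = 100,
                                re_mode = c("zero", "average"),
                                le_ages = c(0, 75), a0 = 0.1, ax = 0.5) {
  stopifnot(inherits(model, "rate_model"))
  if (!isTRUE(model$convergence$converged))
    stop("model did not converge; refusing to build life tables")
  re_mode <- match.arg(re_mode)
  quintiles <- paste0("Q", 1:5)
  tables <- lapply(quintiles, function(q) {
    rates_to_lifetable(model_rate_schedule(model, q, open_age, re_mode),
                       a0 = a0, ax = ax)
  })
  names(tables) <- quintiles
  le <- do.call(rbind, lapply(quintiles, function(q) {
    data.frame(sex = sex, stratum = q, at_age = le_ages,
               le = vapply(le_ages, function(a)
                 life_expectancy_at(tables[[q]], a)$le, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  list(tables = tables, le = le)
}

#' Per-area life expectancy from the fitted model
#'
#' Predicts each area's rate schedule as its quintile's fixed-effect
#' prediction plus the area's empirical-Bayes intercept, builds the life
#' table, and returns life expectancy at the requested ages.
#'
#' @inheritParams quintile_lifetables
#' @param areas Area identifiers (default: all areas in the model).
#' @return Data frame: `area_id`, `quintile`, `sex`, `at_age`, `le`.
#' @export
area_lifetables <- function(model, sex = NA_character_, areas = NULL,
                            open_age = 100, le_ages = c(0, 75),
                            a0 = 0.1, ax = 0.5) {
  stopifnot(inherits(model, "rate_model"))
  if (is.null(areas)) areas <- names(model$area_intercepts)
  unknown <- setdiff(areas, names(model$area_intercepts))
  if (length(unknown))
    stop("unknown area(s): ", paste(unknown, collapse = ", "))
  # per-quintile baseline schedule computed once; area adds exp(u)
  base <- lapply(stats::setNames(paste0("Q", 1:5), paste0("Q", 1:5)),
                 function(q) model_rate_schedule(model, q, open_age, "zero"))
  out <- do.call(rbind, lapply(areas, function(a) {
    q <- model$area_quintile[[a]]
    m <- pmax(base[[q]] * exp(model$area_intercepts[[a]]), 1e-12)
    lt <- rates_to_lifetable(m, a0 = a0, ax = ax)
    data.frame(area_id = a, quintile = q, sex = sex, at_age = le_ages,
               le = vapply(le_ages, function(x)
                 life_expectancy_at(lt, x)$le, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Life table from the ground-truth band rates
#'
#' Expands the synthetic hazard's band-average rates (closed 5-year bands
#' plus the survival-weighted open 85+ band) to a single-year step-function
#' schedule and builds the life table. Used to validate the life-table
#' construction against the fine-grid integral oracle
#' [true_life_expectancy()].
#'
#' @param hazard A [hazard_spec()].
#' @param quintile Quintile label.
#' @param a0,ax Separation factors passed to [rates_to_lifetable()].
#' @return A `life_table` with open interval at 85.
#' @export
true_band_lifetable <- function(hazard, quintile, a0 = 0.1, ax = 0.5) {
  lower <- AGE_BANDS_LOWER
  upper <- c(lower[-1], NA)
  band_m <- mapply(function(lo, up)
    band_average_rate(hazard, quintile, lo, up), lower, upper)
  m <- c(rep(band_m[-length(band_m)], each = 5), band_m[length(band_m)])
  rates_to_lifetable(m, a0 = a0, ax = ax)
}
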