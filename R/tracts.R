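# Fixed population age template: shares per 5-year band 0-4 ... 85+,
# resembling a contemporary European age pyramid. Only positivity and full
# band coverage matter for correctness.
AGE_BANDS_LOWER <- seq(0, 85, by = 5)
AGE_TEMPLATE <- c(0.048, 0.050, 0.051, 0.053, 0.058, 0.064, 0.072, 0.079,
                  0.080, 0.075, 0.068, 0.061, 0.055, 0.049, 0.043, 0.037,
                  0.031, 0.026)
AGE_TEMPLATE <- AGE_TEMPLATE / sum(AGE_TEMPLATE)

# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards: every generator is a pure function of its
# arguments and seed, with no global side effects.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic census-tract frame
#'
#' Builds a set of small areas with deprivation quintiles assigned by rank of
#' a simulated deprivation score (so quintile sizes differ by at most one),
#' province membership in contiguous blocks, and strictly positive
#' person-years per 5-year age band (0-4, ..., 85+), sex and calendar year.
#' Area totals are log-normal around `mean_pop` and the age structure follows
#' a fixed template pyramid scaled to each area's total.
#'
#' @param n_areas Number of areas, >= 5.
#' @param n_provinces Number of provinces (areas assigned in blocks).
#' @param mean_pop Mean area population (persons), > 0.
#' @param years Calendar years covered.
#' @param seed Integer seed; the frame is a pure function of the arguments.
#' @param pop_log_sd Log-scale standard deviation of area totals
#'   (default 0.5).
#' @return A data frame with one row per (area, sex, year, band): columns
#'   `area_id`, `province_id`, `quintile`, `sex`, `year`, `age_lower`,
#'   `age_upper` (`NA` for the open 85+ band), `population` (person-years).
#' @export
generate_tracts <- function(n_areas, n_provinces = 5, mean_pop = 1311,
                            years = 2011:2013, seed = 1, pop_log_sd = 0.5) {
  if (n_areas < 5) stop("n_areas must be >= 5 to form deprivation quintiles")
  stopifnot(mean_pop > 0, n_provinces >= 1, length(years) >= 1)
  with_seed(seed, {
    score <- stats::runif(n_areas)
    r <- rank(score, ties.method = "first")
    quintile <- paste0("Q", floor((r - 1) * 5 / n_areas) + 1)
    totals <- pmax(50, round(mean_pop *
      exp(stats::rnorm(n_areas, 0, pop_log_sd) - pop_log_sd^2 / 2)))
    area_id <- sprintf("A%04d", seq_len(n_areas))
    province_id <- sprintf("P%02d",
      ceiling(seq_len(n_areas) * n_provinces / n_areas))
    nb <- length(AGE_BANDS_LOWER)
    grid <- expand.grid(band = seq_len(nb), year = years,
                        sex = c("male", "female"), area = seq_len(n_areas),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(
      area_id = area_id[grid$area],
      province_id = province_id[grid$area],
      quintile = quintile[grid$area],
      sex = grid$sex,
      year = grid$year,
      age_lower = AGE_BANDS_LOWER[grid$band],
      age_upper = c(AGE_BANDS_LOWER[-1], NA)[grid$band],
      population = totals[grid$area] * AGE_TEMPLATE[grid$band] * 0.5,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$area_id, out$sex, out$year, out$age_lower), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate abridged death counts for a tract frame
#'
#' Draws one log-normal frailty per area, `u ~ Normal(0, frailty_sd^2)`, then
#' per (area, sex, year, band) draws
#' `deaths ~ Poisson(person-years x band-average rate x exp(u))`, where the
#' band-average rate integrates the ground-truth hazard over the band
#' ([band_average_rate()], survival-weighted for the open 85+ band). The one
#' frailty per area is shared across sexes and years. Deterministic given
#' `seed`.
#'
#' @param tracts A frame from [generate_tracts()].
#' @param hazard A [hazard_spec()], or a named list
#'   `list(male = ..., female = ...)` of two specs sharing `frailty_sd`.
#' @param seed Integer seed.
#' @return `tracts` with a `deaths` column appended.
#' @export
simulate_counts <- function(tracts, hazard, seed = 1) {
  req <- c("area_id", "quintile", "sex", "year", "age_lower", "age_upper",
           "population")
  if (!all(req %in% names(tracts))) stop("tracts is missing required columns")
  if (inherits(hazard, "hazard_spec")) {
    hz <- list(male = hazard, female = hazard)
  } else {
    stopifnot(is.list(hazard), all(c("male", "female") %in% names(hazard)))
    hz <- hazard
    if (hz$male$frailty_sd != hz$female$frailty_sd)
      stop("male and female hazards must share frailty_sd (one frailty per area)")
  }
  fr_sd <- hz$male$frailty_sd
  # band-average rate lookup per (sex, quintile, band)
  bands <- unique(tracts[, c("age_lower", "age_upper")])
  rate_of <- new.env(parent = emptyenv())
  for (sx in c("male", "female")) {
    for (q in 1:5) {
      for (i in seq_len(nrow(bands))) {
        key <- paste(sx, q, bands$age_lower[i], sep = "_")
        assign(key, band_average_rate(hz[[sx]], q, bands$age_lower[i],
                                      bands$age_upper[i]), envir = rate_of)
      }
    }
  }
  rates <- mapply(function(sx, q, lo) {
    get(paste(sx, quintile_index(q), lo, sep = "_"), envir = rate_of)
  }, tracts$sex, tracts$quintile, tracts$age_lower)
  areas <- sort(unique(tracts$area_id))
  with_seed(seed, {
    u <- stats::rnorm(length(areas), 0, fr_sd)
    names(u) <- areas
    mu <- tracts$population * rates * exp(u[tracts$area_id])
    if (any(!is.finite(mu)) || any(mu < 0))
      stop("expected deaths are not finite and non-negative")
    tracts$deaths <- stats::rpois(nrow(tracts), mu)
    tracts
  })
}

#' Write / read abridged count tables
#'
#' Delimited-text serialization of the abridged count schema: CSV, UTF-8,
#' header row, columns `area_id, province_id, quintile, sex, year, age_lower,
#' age_upper, deaths, population` with `age_upper` empty for the open band
#' and sex coded `"male"`/`"female"`.
#'
#' @param x A count table (as from [simulate_counts()]).
#' @param path File path.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   validated data frame.
#' @export
write_counts <- function(x, path) {
  cols <- c("area_id", "province_id", "quintile", "sex", "year",
            "age_lower", "age_upper", "deaths", "population")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(x[, cols], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_counts(x)
  x
}

validate_counts <- function(x) {
  req <- c("area_id", "sex", "year", "age_lower", "deaths", "population")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("count table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(x$deaths < 0) || any(x$deaths != round(x$deaths)))
    stop("deaths must be non-negative integers")
  if (any(x$population <= 0)) stop("population must be strictly positive")
  key <- paste(x$area_id, x$sex, x$year, x$age_lower)
  if (anyDuplicated(key)) stop("(area, sex, year, band) rows must be unique")
  invisible(x)
}
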