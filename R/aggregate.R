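#' Population-weighted province life expectancy
#'
#' Province life expectancy is the population-weighted mean of its areas'
#' life expectancies, `sum(LE_i w_i) / sum(w_i)`, with weights the areas'
#' person-years over the study period.
#'
#' @param area_les Data frame from [area_lifetables()] (columns `area_id`,
#'   `at_age`, `le`, optionally `sex`).
#' @param lookup Data frame with `area_id`, `province_id`, `weight`
#'   (person-years, > 0); every area in `area_les` must be mapped.
#' @return Data frame: `province_id`, (`sex`,) `at_age`, `le`.
#' @export
province_le <- function(area_les, lookup) {
  stopifnot(all(c("area_id", "at_age", "le") %in% names(area_les)),
            all(c("area_id", "province_id", "weight") %in% names(lookup)))
  if (any(lookup$weight <= 0)) stop("lookup weights must be > 0")
  unmapped <- setdiff(unique(area_les$area_id), lookup$area_id)
  if (length(unmapped))
    stop("areas missing from lookup: ", paste(unmapped, collapse = ", "))
  m <- match(area_les$area_id, lookup$area_id)
  area_les$province_id <- lookup$province_id[m]
  area_les$weight <- lookup$weight[m]
  keys <- intersect(c("province_id", "sex", "at_age"), names(area_les))
  num <- stats::aggregate(list(wle = area_les$le * area_les$weight),
                          area_les[, keys, drop = FALSE], sum)
  den <- stats::aggregate(list(w = area_les$weight),
                          area_les[, keys, drop = FALSE], sum)
  out <- num
  out$le <- num$wle / den$w
  out$wle <- NULL
  rownames(out) <- NULL
  out
}

#' Rank-based life-expectancy quintiles
#'
#' Bins units (census tracts or provinces) into five groups by rank of life
#' expectancy: Q1 is the 20% of units with the lowest LE, Q5 the highest.
#' Bin sizes differ by at most one; ties in LE are broken by unit id
#' (lexicographic) for determinism.
#'
#' @param values Data frame with `unit_id` and `le` (>= 5 rows).
#' @return The input with an `le_quintile` column (`"Q1"`..`"Q5"`), sorted
#'   by rank.
#' @export
le_quintile_bins <- function(values) {
  stopifnot(all(c("unit_id", "le") %in% names(values)))
  n <- nrow(values)
  if (n < 5) stop("at least 5 units are required to form quintiles")
  ord <- order(values$le, values$unit_id)
  out <- values[ord, , drop = FALSE]
  out$le_quintile <- paste0("Q", floor((seq_len(n) - 1) * 5 / n) + 1)
  rownames(out) <- NULL
  out
}
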