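#' Restricted cubic spline specification
#'
#' Knot positions and centring age for the restricted cubic spline of age
#' used in the rate-smoothing model. The basis dimension is the number of
#' knots minus one (one linear column plus k - 2 restricted cubic columns).
#'
#' @param knots Strictly increasing knot ages in years, at least 3.
#' @param center_age Reference age subtracted from the linear column
#'   (default 60).
#' @return Object of class `spline_spec`.
#' @export
spline_spec <- function(knots = c(2, 12, 22, 32, 42, 52, 67, 82),
                        center_age = 60) {
  knots <- as.numeric(knots)
  if (length(knots) < 3) stop("at least 3 knots are required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  structure(list(knots = knots, center_age = center_age,
                 basis_dimension = length(knots) - 1L),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("Restricted cubic spline: %d knots at {%s}, centred at %g\n",
              length(x$knots), paste(x$knots, collapse = ", "),
              x$center_age))
  invisible(x)
}

#' Restricted cubic spline basis (Harrell parameterization)
#'
#' One row per age, `k - 1` columns for `k` knots. The first column is the
#' linear term `age - center_age`; columns `j = 1..k-2` are the truncated
#' cubic terms
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'       + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2,}
#' which makes the fitted function linear in age below the first and above
#' the last knot.
#'
#' @param ages Numeric vector of ages in years (non-empty).
#' @param spec A [spline_spec()].
#' @return Matrix `length(ages) x (k - 1)` with columns `age`, `age1`, ...
#' @export
rcs_basis <- function(ages, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (length(ages) == 0) stop("ages must be non-empty")
  t <- spec$knots
  k <- length(t)
  norm2 <- (t[k] - t[1])^2
  pos3 <- function(x) pmax(x, 0)^3
  out <- matrix(0, length(ages), k - 1)
  out[, 1] <- ages - spec$center_age
  r <- t[k] - t[k - 1]
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(ages - t[j]) -
                     pos3(ages - t[k - 1]) * (t[k] - t[j]) / r +
                     pos3(ages - t[k]) * (t[k - 1] - t[j]) / r) / norm2
  }
  colnames(out) <- c("age", paste0("age", seq_len(k - 2)))
  out
}

# Fixed-effect design rows for given ages and quintile labels: intercept,
# spline columns, Q2..Q5 indicators, full spline x quintile interaction.
# Shared by build_design() and predict_rates() so fitting and prediction can
# never drift apart.
fixed_matrix <- function(age, quintile, spec) {
  S <- rcs_basis(age, spec)
  k1 <- ncol(S)
  q <- factor(quintile, levels = paste0("Q", 1:5))
  if (anyNA(q)) stop("unknown quintile label(s): ",
                     paste(unique(quintile[is.na(q)]), collapse = ", "))
  Qi <- sapply(paste0("Q", 2:5), function(l) as.numeric(q == l))
  if (is.null(dim(Qi))) Qi <- matrix(Qi, nrow = 1,
                                     dimnames = list(NULL, paste0("Q", 2:5)))
  inter <- matrix(0, length(age), 4 * k1)
  cn <- character(4 * k1)
  for (i in 1:4) {
    cols <- (i - 1) * k1 + seq_len(k1)
    inter[, cols] <- S * Qi[, i]
    cn[cols] <- paste0("Q", i + 1, ":", colnames(S))
  }
  colnames(inter) <- cn
  cbind(`(Intercept)` = 1, S, Qi, inter)
}

#' Build the Poisson mixed-model design from an abridged count table
#'
#' One design row per table row (area, band, year). The fixed part is:
#' intercept, restricted cubic spline of the band's representative age,
#' quintile indicators for Q2..Q5 (Q1 reference), and the full spline by
#' quintile interaction (each spline column times each indicator). Offset is
#' log person-years; areas index the random intercept.
#'
#' Representative age is the band midpoint (`age_lower + 2.5` for the 5-year
#' bands); the open 85+ band is assigned `open_band_age` (default 90, an
#' approximation to the deaths-weighted mean age in that band).
#'
#' @param table Count table with `quintile`, `age_lower`, `age_upper`,
#'   `deaths`, `population`, `area_id` columns (one sex at a time).
#' @param spec A [spline_spec()].
#' @param open_band_age Representative age of the open band.
#' @return Object of class `model_design`: list with `X` (fixed design),
#'   `y`, `offset`, `area` (factor), `rows` (age/quintile per row), `spec`,
#'   `open_band_age`.
#' @export
build_design <- function(table, spec = spline_spec(), open_band_age = 90) {
  if (!"quintile" %in% names(table)) stop("table must have a quintile column")
  validate_counts(table)
  bad <- setdiff(unique(table$quintile), paste0("Q", 1:5))
  if (length(bad))
    stop("unknown quintile label(s): ", paste(bad, collapse = ", "))
  if (length(unique(table$sex)) > 1)
    stop("design must be built per sex; filter the table first")
  age <- ifelse(is.na(table$age_upper),
                open_band_age,
                (table$age_lower + table$age_upper) / 2)
  X <- fixed_matrix(age, table$quintile, spec)
  structure(list(X = X, y = table$deaths, offset = log(table$population),
                 area = factor(table$area_id),
                 rows = data.frame(age = age,
                                   quintile = as.character(table$quintile),
                                   stringsAsFactors = FALSE),
                 spec = spec, open_band_age = open_band_age),
            class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("Poisson rate-model design: %d rows, %d fixed columns, %d areas\n",
              nrow(x$X), ncol(x$X), nlevels(x$area)))
  invisible(x)
}
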