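#' Predict smoothed mortality rates with delta-method intervals
#'
#' Evaluates the fitted model's linear predictor at given exact ages for one
#' deprivation quintile: `eta = x' beta` plus, if `area_id` is given, that
#' area's empirical-Bayes intercept (otherwise the random intercept is set
#' to 0, the population-median area). The rate is `exp(eta)`; the standard
#' error of the log rate is `sqrt(x' V x)` with `V` the fixed-effect
#' covariance, and the confidence interval is the delta-method interval on
#' the rate scale, `exp(eta +/- z * se)`.
#'
#' @param model A [fit_poisson_mixed()] fit.
#' @param ages Ages in years, within [0, 110].
#' @param quintile Single quintile label `"Q1"`..`"Q5"`.
#' @param area_id Optional area identifier whose empirical-Bayes intercept
#'   is added.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `age`, `quintile`, `rate` (per person-year),
#'   `se_log_rate`, `ci_low`, `ci_high`, and `area_id` when given.
#' @export
predict_rates <- function(model, ages, quintile, area_id = NULL,
                          level = 0.95) {
  stopifnot(inherits(model, "rate_model"))
  if (!isTRUE(model$convergence$converged))
    warning("model did not converge; predictions may be unreliable")
  if (any(ages < 0 | ages > 110))
    stop("ages must lie within [0, 110]")
  qlab <- paste0("Q", quintile_index(quintile))
  X <- fixed_matrix(ages, rep(qlab, length(ages)), model$spec)
  u <- 0
  if (!is.null(area_id)) {
    if (!area_id %in% names(model$area_intercepts))
      stop("unknown area: ", area_id)
    u <- model$area_intercepts[[area_id]]
  }
  eta <- drop(X %*% model$beta) + u
  se <- sqrt(pmax(0, rowSums((X %*% model$vcov_beta) * X)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(age = ages, quintile = qlab, rate = exp(eta),
                    se_log_rate = se,
                    ci_low = exp(eta - z * se), ci_high = exp(eta + z * se),
                    stringsAsFactors = FALSE)
  if (!is.null(area_id)) out$area_id <- area_id
  out
}

#' Observed versus fitted rates by age band and quintile
#'
#' Pairs the observed stratum rates (deaths and person-years pooled over
#' areas and years within each age band by quintile) with the
#' population-weighted mean of the model's per-row predicted rates
#' (including each area's empirical-Bayes intercept), and summarizes the
#' agreement as a mean absolute error.
#'
#' @param model A [fit_poisson_mixed()] fit.
#' @param table The count table (one sex) the model was fitted to.
#' @return List: `table` (age_lower, quintile, observed, fitted,
#'   person_years) and `mae`.
#' @export
goodness_of_fit <- function(model, table) {
  stopifnot(inherits(model, "rate_model"))
  validate_counts(table)
  age <- ifelse(is.na(table$age_upper), model$open_band_age,
                (table$age_lower + table$age_upper) / 2)
  X <- fixed_matrix(age, table$quintile, model$spec)
  u <- model$area_intercepts[table$area_id]
  u[is.na(u)] <- 0
  pred <- exp(drop(X %*% model$beta) + u)
  key <- list(age_lower = table$age_lower, quintile = table$quintile)
  obs_d <- stats::aggregate(list(deaths = table$deaths), key, sum)
  obs_p <- stats::aggregate(list(py = table$population), key, sum)
  fit_w <- stats::aggregate(list(wpred = pred * table$population), key, sum)
  out <- data.frame(age_lower = obs_d$age_lower, quintile = obs_d$quintile,
                    observed = obs_d$deaths / obs_p$py,
                    fitted = fit_w$wpred / obs_p$py,
                    person_years = obs_p$py, stringsAsFactors = FALSE)
  out <- out[order(out$quintile, out$age_lower), ]
  rownames(out) <- NULL
  list(table = out, mae = mean(abs(out$observed - out$fitted)))
}

#' Serialize / restore a fitted rate model
#'
#' Writes the fitted fixed effects, their covariance, the random-intercept
#' standard deviation, the empirical-Bayes area intercepts, the spline
#' specification and the area-to-quintile map to a JSON file, and restores a
#' `rate_model` from such a file. The file is self-contained: the life-table
#' stage can run from it without refitting.
#'
#' @param model A `rate_model`.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `rate_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rate_model"))
  obj <- list(
    beta = as.list(model$beta),
    vcov_beta = unname(model$vcov_beta),
    sigma_u = model$sigma_u,
    area_intercepts = as.list(model$area_intercepts),
    area_quintile = as.list(model$area_quintile),
    knots = model$spec$knots,
    center_age = model$spec$center_age,
    open_band_age = model$open_band_age,
    loglik = model$loglik,
    converged = isTRUE(model$convergence$converged)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$beta)
  V <- as.matrix(obj$vcov_beta)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(
    beta = beta, vcov_beta = V, sigma_u = obj$sigma_u,
    area_intercepts = unlist(obj$area_intercepts),
    loglik = obj$loglik,
    convergence = list(converged = isTRUE(obj$converged),
                       message = "restored from file"),
    spec = spline_spec(obj$knots, obj$center_age),
    open_band_age = obj$open_band_age,
    area_quintile = unlist(obj$area_quintile)
  ), class = "rate_model")
}

#' Cross-validated knot selection
#'
#' K-fold cross-validation over observation rows (folds stratified by
#' quintile and age band) of the Poisson mixed-effects fit for each
#' candidate knot set. Held-out rates are predicted with the training fit
#' (using the area's empirical-Bayes intercept when the area was seen in
#' training, else 0), and candidates are scored by the mean absolute error
#' between observed and predicted rates on the held-out fold, pooled by
#' quintile and age band (deaths and person-years summed before dividing;
#' predictions person-years-weighted) so that the error compares rates
#' rather than the near-zero counts of individual tract rows. Fold errors
#' are averaged. Ties are broken toward fewer knots, then smaller knot
#' ages. If a training fold fails to represent every quintile the data are
#' refolded with a new seed (logged via `message()`).
#'
#' @param table Count table (one sex) with quintiles.
#' @param candidates List of [spline_spec()] objects or numeric knot
#'   vectors (given vectors share `center_age`).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param center_age Centring age applied to plain knot vectors.
#' @param open_band_age Representative age of the open band.
#' @param ... Passed to [fit_poisson_mixed()].
#' @return List: `spec` (the chosen [spline_spec()]), `cv` (data frame of
#'   candidate knots and mean CV MAE), `n_folds`, `seed`.
#' @export
select_knots <- function(table, candidates, n_folds = 5, seed = 1,
                         center_age = 60, open_band_age = 90, ...) {
  if (length(candidates) < 1) stop("at least one candidate is required")
  specs <- lapply(candidates, function(cand) {
    if (inherits(cand, "spline_spec")) cand
    else spline_spec(cand, center_age = center_age)
  })
  validate_counts(table)
  n <- nrow(table)
  cell <- interaction(table$quintile, table$age_lower, drop = TRUE)
  quintiles_present <- sort(unique(table$quintile))

  make_folds <- function(s) {
    with_seed(s, {
      fold <- integer(n)
      for (cl in levels(cell)) {
        i <- which(cell == cl)
        i <- i[sample.int(length(i))]
        fold[i] <- ((seq_along(i) + sample.int(n_folds, 1) - 1) %% n_folds) + 1
      }
      fold
    })
  }
  fold <- make_folds(seed)
  tries <- 0
  repeat {
    ok <- all(vapply(seq_len(n_folds), function(f) {
      train <- table[fold != f, ]
      all(quintiles_present %in% train$quintile) &&
        length(unique(train$area_id)) >= 2
    }, logical(1)))
    if (ok) break
    tries <- tries + 1
    if (tries > 10) stop("could not build folds representing every quintile")
    message("refolding: a training fold missed a quintile (try ", tries, ")")
    fold <- make_folds(seed + tries)
  }

  cv_mae <- vapply(specs, function(sp) {
    fold_err <- vapply(seq_len(n_folds), function(f) {
      train <- table[fold != f, , drop = FALSE]
      test <- table[fold == f, , drop = FALSE]
      fit <- fit_poisson_mixed(build_design(train, sp, open_band_age), ...)
      age <- ifelse(is.na(test$age_upper), open_band_age,
                    (test$age_lower + test$age_upper) / 2)
      X <- fixed_matrix(age, test$quintile, sp)
      u <- fit$area_intercepts[test$area_id]
      u[is.na(u)] <- 0
      pred <- exp(drop(X %*% fit$beta) + u)
      key <- list(quintile = test$quintile, age_lower = test$age_lower)
      obs_d <- stats::aggregate(list(d = test$deaths), key, sum)
      obs_p <- stats::aggregate(list(py = test$population), key, sum)
      fit_w <- stats::aggregate(list(wp = pred * test$population), key, sum)
      mean(abs(obs_d$d / obs_p$py - fit_w$wp / obs_p$py))
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))

  nk <- vapply(specs, function(s) length(s$knots), integer(1))
  lex <- vapply(specs, function(s)
    paste(formatC(s$knots, width = 10, format = "f"), collapse = ","),
    character(1))
  ord <- order(round(cv_mae, 12), nk, lex)
  best <- ord[1]
  cv <- data.frame(
    candidate = seq_along(specs),
    knots = vapply(specs, function(s) paste(s$knots, collapse = ","),
                   character(1)),
    n_knots = nk, cv_mae = cv_mae, stringsAsFactors = FALSE)
  list(spec = specs[[best]], cv = cv, n_folds = n_folds, seed = seed)
}
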