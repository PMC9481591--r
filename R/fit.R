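#' Fit the Poisson mixed-effects rate model
#'
#' Maximizes the Laplace-approximated marginal likelihood of the Poisson
#' log-linear model with offset and a Normal(0, sigma_u^2) random intercept
#' per area. The inner loop is penalized iteratively reweighted least squares
#' (PIRLS) jointly in the fixed effects and the area intercepts at fixed
#' sigma_u, exploiting the diagonal random-effect Hessian through a Schur
#' complement; the outer loop is one-dimensional maximization of the Laplace
#' objective over sigma_u. The fixed-effect covariance is the fixed-effect
#' block of the inverse joint Hessian at the optimum (conditional on the
#' estimated sigma_u).
#'
#' The Laplace objective in the numerically stable form used here is
#' \deqn{\ell(\sigma) = \ell_{Pois}(\hat\beta, \hat u)
#'   - \|\hat u\|^2 / (2\sigma^2)
#'   - \tfrac12 \sum_j \log(1 + \sigma^2 d_j),}
#' with \eqn{d_j} the area sums of the Poisson weights; its limit at
#' \eqn{\sigma = 0} is the plain Poisson GLM log-likelihood, so the boundary
#' is handled continuously.
#'
#' @param design A [build_design()] object.
#' @param tol Convergence tolerance on successive (penalized) log-likelihood
#'   values (default 1e-8).
#' @param max_iter Maximum inner PIRLS iterations per sigma evaluation
#'   (default 200).
#' @param sigma_max Upper bound of the sigma_u search (default 3).
#' @param fix_sigma Optional fixed value of sigma_u (e.g. 0 reduces the fit
#'   to an ordinary Poisson GLM by IRLS).
#' @return Object of class `rate_model`: `beta`, `vcov_beta`, `sigma_u`,
#'   `area_intercepts` (empirical-Bayes modes, named by area), `loglik`
#'   (Laplace marginal), `convergence` (status, iteration counts, inner
#'   objective trace of the final fit), plus the spline spec and the
#'   area-to-quintile map needed for prediction.
#' @export
fit_poisson_mixed <- function(design, tol = 1e-8, max_iter = 200,
                              sigma_max = 3, fix_sigma = NULL) {
  stopifnot(inherits(design, "model_design"))
  X <- design$X; y <- design$y; off <- design$offset
  idx <- as.integer(design$area)
  qn <- nlevels(design$area)
  n <- nrow(X); p <- ncol(X)
  if (is.null(fix_sigma) && qn < 2)
    stop("at least 2 areas are required for a random-intercept fit")
  if (sum(y) == 0) stop("all death counts are zero; nothing to fit")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fixed design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }

  pois_ll <- function(mu) sum(stats::dpois(y, mu, log = TRUE))

  # Cholesky solve with escalating ridge fallback: near-singular weighted
  # normal equations can occur transiently when weights collapse on rows
  # supporting a column; the ridge only damps the Newton direction.
  psolve <- function(A, b) {
    ridge <- 0
    for (i in 1:8) {
      ans <- tryCatch({
        ch <- chol(A + diag(ridge, nrow(A)))
        backsolve(ch, forwardsolve(t(ch), b))
      }, error = function(e) NULL)
      if (!is.null(ans)) return(ans)
      ridge <- if (ridge == 0) 1e-8 * mean(diag(A)) else ridge * 100
    }
    stop("weighted normal equations are singular")
  }

  # PIRLS at fixed sigma; returns mode, penalized loglik trace, area weights
  pirls <- function(sigma, beta, u) {
    if (sigma == 0) u <- rep(0, qn)
    inv_s2 <- if (sigma > 0) 1 / sigma^2 else Inf
    eta <- off + drop(X %*% beta) + u[idx]
    mu <- exp(pmin(eta, 30))
    pen <- pois_ll(mu) - if (sigma > 0) sum(u^2) * inv_s2 / 2 else 0
    trace <- pen
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- mu
      A <- crossprod(X * sqrt(w))
      g_beta <- drop(crossprod(X, y - mu))
      if (sigma > 0) {
        M <- rowsum(w * X, idx)                 # q x p
        d <- drop(rowsum(w, idx))
        Dinv <- 1 / (d + inv_s2)
        g_u <- drop(rowsum(y - mu, idx)) - u * inv_s2
        S <- A - crossprod(M, M * Dinv)
        rhs <- g_beta - drop(crossprod(M, Dinv * g_u))
        db <- psolve(S, rhs)
        du <- Dinv * (g_u - drop(M %*% db))
      } else {
        db <- psolve(A, g_beta)
        du <- rep(0, qn)
      }
      step <- 1
      repeat {
        beta_new <- beta + step * db
        u_new <- u + step * du
        eta <- off + drop(X %*% beta_new) + u_new[idx]
        mu_new <- exp(pmin(eta, 30))
        pen_new <- pois_ll(mu_new) -
          if (sigma > 0) sum(u_new^2) * inv_s2 / 2 else 0
        if (is.finite(pen_new) && pen_new >= pen - 1e-10) break
        step <- step / 2
        if (step < 1e-10) { pen_new <- pen; beta_new <- beta; u_new <- u
                            mu_new <- mu; break }
      }
      delta <- pen_new - pen
      beta <- beta_new; u <- u_new; mu <- mu_new
      trace <- c(trace, pen_new)
      if (abs(delta) < tol) { converged <- TRUE; pen <- pen_new; break }
      pen <- pen_new
    }
    list(beta = beta, u = u, mu = mu, pen = pen, trace = trace,
         iters = it, converged = converged)
  }

  # Laplace marginal log-likelihood profile over sigma, warm-started
  # initialize beta by weighted least squares of the empirical log rates
  w0 <- y + 0.1
  z0 <- log(w0 / exp(off))
  cur_beta <- drop(psolve(crossprod(X * sqrt(w0)), crossprod(X, w0 * z0)))
  cur_u <- rep(0, qn)
  any_inner_fail <- FALSE
  outer_evals <- 0L
  lap <- function(sigma) {
    fit <- pirls(sigma, cur_beta, cur_u)
    cur_beta <<- fit$beta; cur_u <<- fit$u
    if (!fit$converged) any_inner_fail <<- TRUE
    outer_evals <<- outer_evals + 1L
    ll <- pois_ll(fit$mu)
    if (sigma > 0) {
      d <- drop(rowsum(fit$mu, idx))
      ll <- ll - sum(fit$u^2) / (2 * sigma^2) - 0.5 * sum(log1p(sigma^2 * d))
    }
    ll
  }

  if (!is.null(fix_sigma)) {
    sigma_hat <- fix_sigma
    loglik <- lap(sigma_hat)
  } else {
    ll0 <- lap(0)
    opt <- stats::optimize(lap, interval = c(1e-6, sigma_max),
                           maximum = TRUE, tol = 1e-4)
    if (opt$objective > ll0) {
      sigma_hat <- opt$maximum
      loglik <- opt$objective
    } else {
      sigma_hat <- 0
      loglik <- ll0
    }
  }
  final <- pirls(sigma_hat, cur_beta, cur_u)
  if (!final$converged)
    warning("inner PIRLS did not converge within max_iter")
  beta <- final$beta; u <- final$u; mu <- final$mu
  w <- mu
  A <- crossprod(X * sqrt(w))
  if (sigma_hat > 0) {
    M <- rowsum(w * X, idx)
    d <- drop(rowsum(w, idx))
    Dinv <- 1 / (d + 1 / sigma_hat^2)
    V <- psolve(A - crossprod(M, M * Dinv), diag(p))
  } else {
    V <- psolve(A, diag(p))
  }
  V <- (V + t(V)) / 2
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  names(u) <- levels(design$area)
  aq <- design$rows$quintile[match(levels(design$area),
                                   as.character(design$area))]
  names(aq) <- levels(design$area)
  structure(list(
    beta = beta, vcov_beta = V, sigma_u = sigma_hat,
    area_intercepts = u, loglik = loglik,
    convergence = list(converged = final$converged && !any_inner_fail,
                       inner_iterations = final$iters,
                       outer_evaluations = outer_evals,
                       inner_objective_trace = final$trace,
                       message = if (final$converged) "converged"
                                 else "inner PIRLS hit max_iter"),
    spec = design$spec, open_band_age = design$open_band_age,
    area_quintile = aq
  ), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Poisson mixed-effects rate model (Laplace)\n")
  cat(sprintf("  %d fixed effects, %d areas; sigma_u = %.4f\n",
              length(x$beta), length(x$area_intercepts), x$sigma_u))
  cat(sprintf("  knots: {%s}, centred at %g; open band at age %g\n",
              paste(x$spec$knots, collapse = ", "), x$spec$center_age,
              x$open_band_age))
  cat(sprintf("  marginal log-likelihood: %.2f (%s)\n", x$loglik,
              x$convergence$message))
  invisible(x)
}
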