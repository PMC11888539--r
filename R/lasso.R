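# L1-penalized logistic regression path, relaxed refits and hard
# thresholding: the building blocks of the signature estimator.

#' Fit an L1-penalized logistic regression path
#'
#' Minimizes mean logistic deviance plus `lambda * sum(|beta_j|)` (the
#' intercept is unpenalized) for every value of a decreasing penalty path,
#' by cyclic coordinate descent on iteratively reweighted least squares
#' with warm starts, strong-rule screening and a full KKT check at every
#' solution.
#'
#' @param X numeric matrix (samples x features), columns standardized.
#' @param y binary response (0/1), both classes present.
#' @param lambda decreasing positive penalty sequence, or `NULL` to build
#'   one from `lambda_max = max |<x_j, y - ybar>| / n`.
#' @param nlambda,lambda_min_ratio path construction when `lambda` is
#'   `NULL`.
#' @param tol coordinate-descent convergence tolerance.
#' @param kkt_tol KKT feasibility tolerance (default 1e-8; solutions are
#'   verified to satisfy the KKT conditions to within 1e-7).
#' @param dfmax once a solution's active set exceeds this size, the
#'   remaining (smaller) lambdas are not solved and are flagged in
#'   `truncated` (glmnet-style early path exit; default unlimited).
#' @return Object of class `lasso_path`: `lambda`, `beta` (features x
#'   lambda), `a0` (intercepts), `kkt_gap`, and the data dimensions.
#' @export
lasso_logistic_path <- function(X, y, lambda = NULL, nlambda = 15,
                                lambda_min_ratio = 0.1,
                                tol = 1e-10, kkt_tol = 1e-8, dfmax = Inf) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (!all(c(0, 1) %in% y)) stop("both classes must be present")
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  if (any(lambda <= 0) || any(diff(lambda) >= 0)) {
    stop("lambda must be a strictly decreasing positive sequence")
  }
  fit <- cd_lasso_logistic_path(X, y, lambda, tol = tol, kkt_tol = kkt_tol,
                                dfmax = if (is.finite(dfmax)) as.integer(dfmax) else -1L)
  if (any(fit$converged == 0L)) {
    bad <- which(fit$converged == 0L)[1]
    stop(sprintf("coordinate descent did not converge at lambda = %.6g (KKT gap %.3g)",
                 lambda[bad], fit$kkt_gap[bad]))
  }
  rownames(fit$beta) <- colnames(X)
  structure(list(lambda = lambda, beta = fit$beta, a0 = as.numeric(fit$a0),
                 kkt_gap = as.numeric(fit$kkt_gap),
                 truncated = as.logical(fit$truncated),
                 n = nrow(X), p = ncol(X)),
            class = "lasso_path")
}

#' Penalized logistic objective
#'
#' Mean logistic negative log-likelihood plus `lambda * sum(|beta|)`;
#' the quantity minimized by [lasso_logistic_path()]. Exposed so fits can
#' be compared against independent convex solvers.
#'
#' @param X,y data as in [lasso_logistic_path()].
#' @param a0 intercept.
#' @param beta coefficient vector.
#' @param lambda penalty.
#' @return Scalar objective value.
#' @export
penalized_logistic_objective <- function(X, y, a0, beta, lambda) {
  eta <- as.numeric(a0 + X %*% beta)
  # log(1 + exp(eta)) - y*eta, computed stably
  nll <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  nll + lambda * sum(abs(beta))
}

# Unpenalized logistic refit on a support, with a ridge-stabilized
# fallback when the refit is separable or fails to converge. Returns the
# coefficients aligned with `support` (not full-length).
refit_support <- function(X, y, support, ridge = 1e-6, warn = TRUE) {
  if (length(support) == 0L) {
    return(list(a0 = qlogis(mean(y)), b = numeric(0), stabilized = FALSE))
  }
  Xs <- X[, support, drop = FALSE]
  fit <- NULL
  warned <- FALSE
  withCallingHandlers(
    fit <- tryCatch(glm.fit(cbind(1, Xs), y, family = binomial(),
                               control = list(maxit = 15)),
                    error = function(e) NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  separable <- is.null(fit) || !fit$converged || warned ||
    any(!is.finite(fit$coefficients)) || max(abs(fit$coefficients)) > 1e3
  if (!separable) {
    cf <- fit$coefficients
  } else {
    if (warn) warning("separable or ill-conditioned refit; using ridge-stabilized refit")
    cf <- ridge_logistic(cbind(1, Xs), y, ridge = ridge)
  }
  list(a0 = cf[1], b = unname(cf[-1]), stabilized = separable)
}

refit_logistic <- function(X, y, support, ridge = 1e-6, warn = TRUE) {
  rf <- refit_support(X, y, support, ridge = ridge, warn = warn)
  beta <- numeric(ncol(X))
  beta[support] <- rf$b
  list(a0 = rf$a0, beta = beta, stabilized = rf$stabilized)
}

# Newton/IRLS logistic fit with a small ridge penalty on all coefficients
# except the intercept; always well defined. Under separation the
# penalized optimum sits at very large coefficients, so iteration stops
# once the penalized log-likelihood no longer improves meaningfully.
ridge_logistic <- function(Xd, y, ridge = 1e-6, maxit = 20, tol = 1e-10) {
  k <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, k - 1)), k)
  b <- numeric(k)
  b[1] <- qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xd %*% b)
    pf <- plogis(eta)
    w <- pmax(pf * (1 - pf), 1e-10)
    g <- crossprod(Xd, y - pf) - pen %*% b
    H <- crossprod(Xd * w, Xd) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    b <- b + step
    obj <- -sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) -
      0.5 * sum(diag(pen) * b^2)
    if (max(abs(step)) < tol || abs(obj - obj_old) < 1e-8) break
    obj_old <- obj
  }
  as.numeric(b)
}

#' Relaxed-lasso logistic fit on a given support
#'
#' The standard relaxed-lasso blend
#' `beta(gamma) = gamma * beta_lasso + (1 - gamma) * beta_refit`, where
#' `beta_refit` is the unpenalized logistic fit restricted to the support.
#' `gamma = 1` recovers the lasso fit, `gamma = 0` the fully relaxed
#' refit; "mostly relaxed" corresponds to `gamma` near 0. A separable
#' refit falls back to a ridge-stabilized fit (penalty 1e-6) with a
#' warning. An empty support yields the intercept-only model.
#'
#' @param X,y data (columns of `X` standardized).
#' @param support integer indices of the active features.
#' @param gamma relaxation weight in `[0, 1]`.
#' @param beta_lasso,a0_lasso the lasso solution being relaxed
#'   (full-length coefficient vector and intercept). Only the entries on
#'   `support` participate in the blend.
#' @return List with `a0`, `beta` (full-length, zero off-support) and
#'   `stabilized` flag.
#' @export
relax_fit <- function(X, y, support, gamma, beta_lasso, a0_lasso) {
  stopifnot(gamma >= 0, gamma <= 1)
  rf <- refit_logistic(X, y, support)
  bl <- numeric(ncol(X))
  bl[support] <- beta_lasso[support]
  list(a0 = gamma * a0_lasso + (1 - gamma) * rf$a0,
       beta = gamma * bl + (1 - gamma) * rf$beta,
       stabilized = rf$stabilized)
}

#' Hard-threshold a coefficient vector
#'
#' Sets to zero every coefficient with `|beta_j| < tau` (standardized
#' scale); `tau = 0` is the identity. The surviving support is intended to
#' be refit via [relax_fit()] at the current relaxation weight, which the
#' model-fitting routines do automatically.
#'
#' @param beta coefficient vector.
#' @param tau non-negative threshold.
#' @return List with `beta` (thresholded) and `support` (surviving
#'   indices).
#' @export
hard_threshold <- function(beta, tau) {
  stopifnot(tau >= 0)
  if (tau > 0) beta[abs(beta) < tau] <- 0
  list(beta = beta, support = which(beta != 0))
}
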