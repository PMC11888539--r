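# The signature estimator: hard-thresholded, mostly relaxed,
# LASSO-constrained logistic regression, tuned and evaluated by
# leave-one-batch-out (LOBO) cross-validation.

#' Per-gene standardization of log2-CPM expression
#'
#' Fits or applies a transform spec: `log2(CPM + 1)` followed by per-gene
#' centering and scaling (SD floored at a small epsilon, so constant
#' genes map to zero). In fit mode the returned spec stores the training
#' constants; in scoring mode the stored constants are applied unchanged.
#'
#' @param expr gene-by-sample matrix tagged `"cpm"` (or `"log2cpm"`).
#' @param spec a `transform_spec` to apply (scoring mode), or `NULL` to
#'   fit one.
#' @param eps scale floor.
#' @return List with `x` — a samples-by-genes standardized model matrix —
#'   and `spec` (class `transform_spec`: `gene`, `center`, `scale`).
#' @export
transform_expression <- function(expr, spec = NULL, eps = 1e-8) {
  u <- expr_unit(expr)
  l2 <- if (u == "cpm") log2(expr + 1) else if (u == "log2cpm") expr else
    stop("unknown expression unit: ", u)
  if (is.null(spec)) {
    center <- rowMeans(l2)
    scale <- pmax(apply(l2, 1, sd), eps)
    spec <- structure(list(gene = rownames(expr), center = center, scale = scale),
                      class = "transform_spec")
  } else {
    missing <- setdiff(spec$gene, rownames(expr))
    if (length(missing)) {
      stop("genes absent from expression matrix: ", paste(missing, collapse = ", "))
    }
    l2 <- l2[spec$gene, , drop = FALSE]
    center <- spec$center
    scale <- spec$scale
  }
  x <- t((l2 - center) / scale)
  attr(x, "unit") <- NULL
  list(x = x, spec = spec)
}

#' Tuning grid for the signature estimator
#'
#' @param lambda optional decreasing positive penalty sequence; by default
#'   built from the training data (`nlambda` values, log-spaced down to
#'   `lambda_min_ratio * lambda_max`).
#' @param nlambda,lambda_min_ratio path construction parameters.
#' @param gamma relaxation weights in `[0, 1]`; the default grid is
#'   concentrated near 0 ("mostly relaxed").
#' @param tau hard-threshold values (standardized coefficient scale).
#' @param refit_cap largest support size for which relaxed (`gamma < 1`)
#'   refits are evaluated during grid search. Denser solutions are only
#'   examined as pure lasso fits (`gamma = 1`), since under a small
#'   sparsity budget they can never be selected and their unpenalized
#'   refits are invariably separable.
#' @return Object of class `tuning_grid`.
#' @export
tuning_grid <- function(lambda = NULL, nlambda = 15, lambda_min_ratio = 0.1,
                        gamma = c(0, 0.1, 0.25, 0.5, 1),
                        tau = c(0, 0.05, 0.1, 0.25),
                        refit_cap = 25) {
  if (!is.null(lambda)) {
    if (any(lambda <= 0) || any(diff(lambda) >= 0)) {
      stop("lambda must be strictly decreasing and positive")
    }
  }
  if (length(gamma) == 0 || any(gamma < 0 | gamma > 1)) {
    stop("gamma grid must be non-empty within [0, 1]")
  }
  if (length(tau) == 0 || any(tau < 0)) stop("tau grid must be non-empty, >= 0")
  if (refit_cap < 1) stop("refit_cap must be positive")
  structure(list(lambda = lambda, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 gamma = gamma, tau = tau, refit_cap = refit_cap),
            class = "tuning_grid")
}

grid_lambda <- function(X, y, grid) {
  if (!is.null(grid$lambda)) return(grid$lambda)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  if (lambda_max <= 0) lambda_max <- 1e-3
  exp(seq(log(lambda_max), log(lambda_max * grid$lambda_min_ratio),
          length.out = grid$nlambda))
}

# Fit every (lambda, gamma, tau) grid-point model on one training set.
# Returns a flat list of sparse models; unpenalized refits are cached by
# support. Refit warnings are suppressed here (the stabilized flag is
# kept) to keep grid search quiet.
grid_models <- function(X, y, lambda, gamma, tau, refit_cap = Inf) {
  path <- lasso_logistic_path(X, y, lambda = lambda,
                              dfmax = if (is.finite(refit_cap)) refit_cap else Inf)
  cache <- new.env(parent = emptyenv())
  get_refit <- function(supp) {
    key <- paste0("s", paste(supp, collapse = ","))
    got <- cache[[key]]
    if (is.null(got)) {
      got <- refit_support(X, y, supp, warn = FALSE)
      cache[[key]] <- got
    }
    got
  }
  out <- vector("list", length(lambda) * length(gamma) * length(tau))
  k <- 0L
  for (li in seq_along(lambda)) {
    if (isTRUE(path$truncated[li])) {
      for (i in seq_len(length(gamma) * length(tau))) { k <- k + 1L; out[k] <- list(NULL) }
      next
    }
    supp <- which(path$beta[, li] != 0)
    bl <- path$beta[supp, li]
    a0l <- path$a0[li]
    # an unpenalized refit is only needed (and only sensible) when some
    # gamma < 1 is on the grid and the support is below the refit cap
    rf <- if (any(gamma < 1) && length(supp) <= refit_cap) get_refit(supp)
          else NULL
    for (g in gamma) {
      if (g < 1 && is.null(rf)) {
        for (tv in tau) { k <- k + 1L; out[k] <- list(NULL) }
        next
      }
      if (g == 1) {
        bg <- bl; a0g <- a0l; stab0 <- FALSE
      } else {
        bg <- g * bl + (1 - g) * rf$b
        a0g <- g * a0l + (1 - g) * rf$a0
        stab0 <- rf$stabilized
      }
      for (tv in tau) {
        b2 <- bg; sp <- supp; a02 <- a0g; stab <- stab0
        dead <- FALSE
        if (tv > 0) {
          live <- abs(bg) >= tv & bg != 0
          if (!all(live)) {
            sp <- supp[live]
            if (g == 1) {
              b2 <- bl[live]; a02 <- a0l
            } else if (length(sp) <= refit_cap) {
              rf2 <- get_refit(sp)
              b2 <- g * bl[live] + (1 - g) * rf2$b
              a02 <- g * a0l + (1 - g) * rf2$a0
              stab <- rf2$stabilized
            } else {
              dead <- TRUE
            }
          }
        }
        k <- k + 1L
        if (dead) { out[k] <- list(NULL); next }
        live2 <- b2 != 0
        out[[k]] <- list(lambda_index = li, lambda = lambda[li],
                         gamma = g, tau = tv,
                         support = sp[live2], beta = b2[live2], a0 = a02,
                         stabilized = stab)
      }
    }
  }
  out
}

score_sparse <- function(model, X) {
  if (length(model$support) == 0L) return(rep(model$a0, nrow(X)))
  as.numeric(model$a0 + X[, model$support, drop = FALSE] %*% model$beta)
}

#' Leave-one-batch-out tuning of the signature estimator
#'
#' For every grid point (lambda, gamma, tau), leaves out each batch in
#' turn, fits on the remaining batches and scores the held-out samples.
#' The grid point maximizing the pooled held-out AUC subject to median
#' support size `<= sparsity_budget` is selected; ties are broken toward
#' the sparser model, then the larger lambda, then the smaller gamma,
#' then the larger tau. Folds whose removal empties a class are skipped
#' with a warning.
#'
#' @param X standardized model matrix (samples x genes).
#' @param y binary response.
#' @param batches batch label per sample.
#' @param grid a [tuning_grid()].
#' @param sparsity_budget maximum tolerated median support size
#'   (`Inf` disables the constraint).
#' @return List of class `signature_tuning`: chosen `lambda`, `gamma`,
#'   `tau`, `lambda_index`, the shared `lambda_path`, pooled `inner_auc`,
#'   `median_support`, and the full grid `table`.
#' @export
tune_signature_lobo <- function(X, y, batches, grid = tuning_grid(),
                                sparsity_budget = 6) {
  batches <- as.character(batches)
  ub <- unique(batches)
  if (length(ub) < 2) stop("need at least 2 batches for LOBO tuning")
  lambda <- grid_lambda(X, y, grid)
  ncombo <- length(lambda) * length(grid$gamma) * length(grid$tau)
  scores <- vector("list", ncombo)
  labels <- vector("list", ncombo)
  valid <- rep(TRUE, ncombo)
  suppsize <- matrix(NA_integer_, ncombo, length(ub))
  used <- 0L
  for (bi in seq_along(ub)) {
    tr <- batches != ub[bi]
    if (length(unique(y[tr])) < 2) {
      warning(sprintf("inner fold leaving out batch '%s' empties a class; skipped", ub[bi]))
      next
    }
    used <- used + 1L
    models <- grid_models(X[tr, , drop = FALSE], y[tr], lambda,
                          grid$gamma, grid$tau,
                          refit_cap = grid$refit_cap %||% Inf)
    Xte <- X[!tr, , drop = FALSE]
    for (k in seq_len(ncombo)) {
      if (is.null(models[[k]])) { valid[k] <- FALSE; next }
      scores[[k]] <- c(scores[[k]], score_sparse(models[[k]], Xte))
      labels[[k]] <- c(labels[[k]], y[!tr])
      suppsize[k, bi] <- length(models[[k]]$support)
    }
  }
  if (used == 0L) stop("all inner folds were skipped; cannot tune")
  med_supp <- apply(suppsize, 1, median, na.rm = TRUE)
  auc <- vapply(seq_len(ncombo), function(k) {
    if (!valid[k]) return(NA_real_)
    auc_rank(scores[[k]], labels[[k]])
  }, numeric(1))
  # grid_models orders lambda (outer), gamma, tau (inner)
  tab <- data.frame(lambda_index = rep(seq_along(lambda),
                                       each = length(grid$gamma) * length(grid$tau)),
                    gamma = rep(rep(grid$gamma, each = length(grid$tau)),
                                times = length(lambda)),
                    tau = rep(grid$tau, times = length(lambda) * length(grid$gamma)))
  tab$lambda <- lambda[tab$lambda_index]
  tab$median_support <- med_supp
  tab$inner_auc <- auc
  eligible <- which(valid & !is.na(auc) & med_supp <= sparsity_budget)
  if (length(eligible) == 0L) eligible <- which(valid & !is.na(auc))
  auc_r <- round(auc, 10)
  ord <- eligible[order(-auc_r[eligible], med_supp[eligible],
                        tab$lambda_index[eligible], tab$gamma[eligible],
                        -tab$tau[eligible])]
  best <- ord[1]
  structure(list(lambda = tab$lambda[best], gamma = tab$gamma[best],
                 tau = tab$tau[best], lambda_index = tab$lambda_index[best],
                 lambda_path = lambda, inner_auc = auc[best],
                 median_support = med_supp[best],
                 sparsity_budget = sparsity_budget, table = tab),
            class = "signature_tuning")
}

# Fit the model at one tuned grid point on a full training set: lasso at
# the chosen lambda, relaxed blend at the chosen gamma, hard threshold at
# the chosen tau, and finally a rank-based hard threshold enforcing the
# sparsity budget on the fitted model itself (parsimony is a contract of
# the final signature, not only of the tuning criterion).
fit_at_tuning <- function(X, y, tuning, budget = Inf) {
  path <- lasso_logistic_path(X, y, lambda = tuning$lambda_path)
  li <- tuning$lambda_index
  g <- tuning$gamma
  supp <- which(path$beta[, li] != 0)
  bl <- path$beta[supp, li]
  a0l <- path$a0[li]

  blend <- function(sp) {
    rf <- refit_support(X, y, sp, warn = FALSE)
    keep <- match(sp, supp)
    list(support = sp, beta = g * bl[keep] + (1 - g) * rf$b,
         a0 = g * a0l + (1 - g) * rf$a0, stabilized = rf$stabilized)
  }
  m <- blend(supp)
  if (tuning$tau > 0) {
    live <- abs(m$beta) >= tuning$tau
    if (!all(live)) m <- blend(m$support[live])
  }
  if (is.finite(budget) && length(m$support) > budget) {
    top <- order(abs(m$beta), decreasing = TRUE)[seq_len(budget)]
    m <- blend(sort(m$support[top]))
  }
  live <- m$beta != 0
  list(lambda_index = li, lambda = tuning$lambda, gamma = g, tau = tuning$tau,
       support = m$support[live], beta = m$beta[live], a0 = m$a0,
       stabilized = m$stabilized)
}

#' Nested leave-one-batch-out cross-validation of the signature procedure
#'
#' Estimates the performance of the *entire* tuning-plus-fitting
#' procedure: for each outer batch, the grid is tuned by an inner LOBO
#' over the remaining batches only, the tuned model is fit on those
#' batches, and the held-out batch is scored by it. The pooled CV-AUC is
#' computed on the union of held-out scores, so no sample ever influences
#' its own scorer; per-outer-fold AUCs are reported alongside. The
#' per-gene standardization is refit on each outer training set.
#'
#' @param expr gene-by-sample matrix tagged `"cpm"`.
#' @param labels binary outcome per sample (`NA` samples are dropped).
#' @param batches batch label per sample.
#' @param grid a [tuning_grid()].
#' @param sparsity_budget see [tune_signature_lobo()].
#' @return Object of class `signature_cv`: `cv_auc` (pooled), `folds`
#'   (per-batch: held-out scores and labels, fold AUC, chosen tuning,
#'   selected genes), `fold_auc`, `scores` (pooled, in input sample
#'   order for the retained samples).
#' @export
cv_signature <- function(expr, labels, batches, grid = tuning_grid(),
                         sparsity_budget = 6) {
  if (expr_unit(expr) != "cpm") stop("cv_signature() expects a cpm-scale matrix")
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  y <- as.integer(labels[keep])
  batches <- as.character(batches[keep])
  ub <- unique(batches)
  if (length(ub) < 3) stop("nested LOBO cross-validation needs at least 3 batches")
  folds <- list()
  pooled_scores <- rep(NA_real_, length(y))
  for (b in ub) {
    te <- batches == b
    if (length(unique(y[!te])) < 2) {
      warning(sprintf("outer fold leaving out batch '%s' empties a class; skipped", b))
      next
    }
    tf <- transform_expression(set_unit(expr[, !te, drop = FALSE], "cpm"))
    tuning <- tune_signature_lobo(tf$x, y[!te], batches[!te], grid,
                                  sparsity_budget)
    model <- fit_at_tuning(tf$x, y[!te], tuning, budget = sparsity_budget)
    Xte <- transform_expression(set_unit(expr[, te, drop = FALSE], "cpm"),
                                spec = tf$spec)$x
    sc <- score_sparse(model, Xte)
    pooled_scores[te] <- sc
    folds[[b]] <- list(batch = b, scores = sc, labels = y[te],
                       auc = auc_rank(sc, y[te]),
                       tuning = tuning[c("lambda", "gamma", "tau", "inner_auc")],
                       genes = colnames(tf$x)[model$support],
                       coefficients = setNames(model$beta,
                                               colnames(tf$x)[model$support]))
  }
  scored <- !is.na(pooled_scores)
  # each fold is scored by a different model, so raw scores carry
  # fold-specific offsets; the headline pooled AUC removes them by
  # centering each fold's held-out scores before pooling
  centered <- pooled_scores
  for (f in folds) {
    te <- batches == f$batch
    centered[te] <- centered[te] - mean(centered[te])
  }
  structure(list(cv_auc = auc_rank(centered[scored], y[scored]),
                 cv_auc_uncentered = auc_rank(pooled_scores[scored], y[scored]),
                 fold_auc = vapply(folds, `[[`, numeric(1), "auc"),
                 folds = folds,
                 scores = data.frame(sample_id = colnames(expr)[scored],
                                     batch = batches[scored],
                                     score = pooled_scores[scored],
                                     label = y[scored],
                                     stringsAsFactors = FALSE)),
            class = "signature_cv")
}

#' Fit the final gene signature
#'
#' Tuning is chosen by a (non-nested) leave-one-batch-out over all
#' batches, then the model is fit once on all training data at the chosen
#' (lambda, gamma, tau). The returned model carries the per-gene transform
#' constants of its selected genes, so it is a pure function of the raw
#' expression of those genes.
#'
#' @inheritParams cv_signature
#' @return Object of class `signature_model` with elements `genes`,
#'   `coefficients` (standardized log2-CPM scale), `intercept`,
#'   `transform` (center/scale restricted to the selected genes),
#'   `tuning`, `n_features`, `n_samples`.
#' @export
fit_signature <- function(expr, labels, batches, grid = tuning_grid(),
                          sparsity_budget = 6) {
  if (expr_unit(expr) != "cpm") stop("fit_signature() expects a cpm-scale matrix")
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  y <- as.integer(labels[keep])
  batches <- as.character(batches[keep])
  tf <- transform_expression(set_unit(expr, "cpm"))
  tuning <- tune_signature_lobo(tf$x, y, batches, grid, sparsity_budget)
  model <- fit_at_tuning(tf$x, y, tuning, budget = sparsity_budget)
  genes <- colnames(tf$x)[model$support]
  structure(list(
    genes = genes,
    coefficients = setNames(model$beta, genes),
    intercept = model$a0,
    transform = structure(list(gene = genes,
                               center = tf$spec$center[model$support],
                               scale = tf$spec$scale[model$support]),
                          class = "transform_spec"),
    tuning = list(lambda = tuning$lambda, gamma = tuning$gamma,
                  tau = tuning$tau, inner_auc = tuning$inner_auc,
                  sparsity_budget = tuning$sparsity_budget),
    coefficient_scale = "standardized log2(CPM+1)",
    n_features = ncol(tf$x), n_samples = nrow(tf$x)
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, digits = 3, ...) {
  cat(sprintf("Gene signature: %d gene(s) selected from %d (n = %d samples)\n",
              length(x$genes), x$n_features, x$n_samples))
  cat(sprintf("  tuning: lambda = %.4g, gamma = %g, tau = %g (inner LOBO AUC %.3f)\n",
              x$tuning$lambda, x$tuning$gamma, x$tuning$tau, x$tuning$inner_auc))
  if (length(x$genes)) {
    cat("  coefficients (", x$coefficient_scale, "):\n", sep = "")
    print(round(x$coefficients, digits))
  } else {
    cat("  intercept-only model\n")
  }
  cat(sprintf("  intercept: %.*f\n", digits, x$intercept))
  invisible(x)
}

#' @export
coef.signature_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Risk scores for a fitted signature
#'
#' Applies the model's stored transform (log2(CPM+1), center, scale of the
#' selected genes) and the linear form
#' `score = intercept + sum_j beta_j * x_j`. Deterministic; errors if any
#' model gene is absent.
#'
#' @param object a `signature_model`.
#' @param expr gene-by-sample matrix tagged `"cpm"` containing the model
#'   genes.
#' @param ... unused.
#' @return Named numeric vector of risk scores, one per sample.
#' @export
predict.signature_model <- function(object, expr, ...) {
  if (expr_unit(expr) != "cpm") stop("predict() expects a cpm-scale matrix")
  if (any(expr < 0)) stop("negative CPM values")
  x <- transform_expression(expr, spec = object$transform)$x
  setNames(as.numeric(object$intercept + x %*% object$coefficients),
           colnames(expr))
}

#' @rdname predict.signature_model
#' @param model a `signature_model`.
#' @export
risk_score <- function(model, expr) predict(model, expr)

#' @export
print.signature_cv <- function(x, digits = 3, ...) {
  cat(sprintf("Nested LOBO cross-validation over %d batches\n", length(x$folds)))
  cat(sprintf("  pooled CV-AUC: %.*f\n", digits, x$cv_auc))
  cat(sprintf("  per-fold AUC: %s\n",
              paste(sprintf("%.3f", x$fold_auc), collapse = ", ")))
  invisible(x)
}
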