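# User-level modelling interface: one call from raw counts to a fitted,
# thresholded signature, with the usual methods on the returned object.

#' Fit a bacterial-vs-nonbacterial gene signature from raw counts
#'
#' The one-call modelling interface. Runs the QC/filter cascade, fits the
#' hard-thresholded mostly-relaxed LASSO-constrained logistic signature
#' with leave-one-batch-out tuning, optionally estimates honest
#' performance by nested LOBO cross-validation, and derives the
#' sensitivity-anchored classification threshold on the training scores.
#' Non-infected controls (class `NI`) are excluded from all supervised
#' steps but are scored and classified at the derived threshold.
#'
#' @param counts gene-by-sample count matrix (genes as rows).
#' @param annotation data frame with `sample_id`, `batch`, `class`
#'   matching the count columns.
#' @param min_cpm,pca_components,pca_sd_multiplier,max_batch_fraction QC
#'   settings passed to [preprocess_counts()].
#' @param grid a [tuning_grid()].
#' @param sparsity_budget maximum median support size during tuning
#'   (default 6 genes).
#' @param target_sensitivity sensitivity floor for the threshold
#'   (default 0.90).
#' @param prevalence prevalence grid for NPV/PPV reporting.
#' @param cv run the nested LOBO cross-validation (default `TRUE`).
#' @return Object of class `bactsig` with elements `model`
#'   (`signature_model`), `cv` (`signature_cv` or `NULL`), `threshold`
#'   (`threshold_report`), `scores` (per-sample data frame including NI
#'   controls), `filter_report`, `train_auc`, `ni_fraction_nonbacterial`.
#' @examples
#' cfg <- sim_config(n_genes = 300,
#'                   n_samples_per_class = c(V = 40, B = 20, VB = 12, NI = 8),
#'                   n_batches = 4, seed = 7)
#' sim <- simulate_cohort(cfg)
#' fit <- bactsig(sim$counts, sim$annotation, cv = FALSE,
#'                grid = tuning_grid(nlambda = 10, gamma = c(0, 1),
#'                                   tau = c(0, 0.1)))
#' print(fit)
#' @export
bactsig <- function(counts, annotation,
                    min_cpm = 2, pca_components = 2, pca_sd_multiplier = 6,
                    max_batch_fraction = 0.5,
                    grid = tuning_grid(), sparsity_budget = 6,
                    target_sensitivity = 0.90,
                    prevalence = seq(0.05, 0.50, by = 0.05),
                    cv = TRUE) {
  cl <- match.call()
  filtered <- preprocess_counts(counts, annotation, min_cpm = min_cpm,
                                pca_components = pca_components,
                                pca_sd_multiplier = pca_sd_multiplier,
                                max_batch_fraction = max_batch_fraction)
  y <- outcome_labels(filtered$annotation)
  cpm <- filtered$cpm
  batches <- filtered$annotation$batch
  cv_res <- if (isTRUE(cv)) cv_signature(cpm, y, batches, grid, sparsity_budget)
            else NULL
  model <- fit_signature(cpm, y, batches, grid, sparsity_budget)
  all_scores <- predict(model, cpm)
  labeled <- !is.na(y)
  thr <- threshold_for_sensitivity(all_scores[labeled], y[labeled],
                                   target_se = target_sensitivity,
                                   prevalence = prevalence)
  score_df <- data.frame(sample_id = filtered$annotation$sample_id,
                         batch = batches,
                         class = filtered$annotation$class,
                         label = y,
                         score = unname(all_scores),
                         call = ifelse(all_scores >= thr$threshold,
                                       "bacterial", "nonbacterial"),
                         stringsAsFactors = FALSE)
  ni <- score_df$class == "NI"
  structure(list(model = model, cv = cv_res, threshold = thr,
                 scores = score_df, filter_report = filtered$report,
                 train_auc = auc_rank(all_scores[labeled], y[labeled]),
                 ni_fraction_nonbacterial =
                   if (any(ni)) mean(score_df$call[ni] == "nonbacterial")
                   else NA_real_,
                 call = cl),
            class = "bactsig")
}

#' @export
print.bactsig <- function(x, ...) {
  cat("Bacterial-vs-nonbacterial gene signature fit\n\n")
  print(x$model)
  if (!is.null(x$cv)) {
    cat(sprintf("\nnested LOBO CV-AUC: %.3f (training AUC %.3f)\n",
                x$cv$cv_auc, x$train_auc))
  } else {
    cat(sprintf("\ntraining AUC: %.3f\n", x$train_auc))
  }
  cat(sprintf("threshold %.3f (target Se >= %.0f%%): Se %.1f%%, Sp %.1f%%\n",
              x$threshold$threshold, 100 * x$threshold$target_se,
              100 * x$threshold$sensitivity, 100 * x$threshold$specificity))
  invisible(x)
}

#' @export
summary.bactsig <- function(object, ...) {
  structure(list(fit = object), class = "summary.bactsig")
}

#' @export
print.summary.bactsig <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n")
  print(f$filter_report)
  cat("\nNPV/PPV over prevalence:\n")
  print(round(f$threshold$predictive_values, 3))
  if (!is.na(f$ni_fraction_nonbacterial)) {
    cat(sprintf("\nnon-infected controls classified nonbacterial: %.0f%%\n",
                100 * f$ni_fraction_nonbacterial))
  }
  if (!is.null(f$cv)) {
    cat("\nper-fold CV gene sets:\n")
    for (fold in f$cv$folds) {
      cat(sprintf("  batch %s (AUC %.3f): %s\n", fold$batch, fold$auc,
                  paste(fold$genes, collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
coef.bactsig <- function(object, ...) coef(object$model)

#' @rdname bactsig
#' @param object a fitted `bactsig` object.
#' @param newdata gene-by-sample count matrix, or a cpm-tagged expression
#'   matrix; `NULL` returns the training scores.
#' @param type `"score"` for risk scores, `"class"` for thresholded
#'   calls.
#' @param ... unused.
#' @export
predict.bactsig <- function(object, newdata = NULL,
                            type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    sc <- setNames(object$scores$score, object$scores$sample_id)
  } else {
    u <- attr(newdata, "unit")
    cpm <- if (is.null(u)) compute_cpm(newdata) else newdata
    sc <- predict(object$model, cpm)
  }
  if (type == "score") sc
  else ifelse(sc >= object$threshold$threshold, "bacterial", "nonbacterial")
}

#' @export
residuals.bactsig <- function(object, ...) {
  df <- object$scores[!is.na(object$scores$label), ]
  p <- plogis(df$score)
  y <- df$label
  d <- -2 * (y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  setNames(sign(y - p) * sqrt(d), df$sample_id)
}

#' @rdname bactsig
#' @param x a fitted `bactsig` object.
#' @export
plot.bactsig <- function(x, ...) {
  df <- x$scores[!is.na(x$scores$label), ]
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  roc <- roc_auc(df$score, df$label)
  plot(roc$points$fpr, roc$points$tpr, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC %.3f)", roc$auc))
  abline(0, 1, lty = 3)
  d1 <- stats::density(df$score[df$label == 1])
  d0 <- stats::density(df$score[df$label == 0])
  plot(d0, col = "blue", main = "risk-score distributions",
       xlab = "risk score",
       xlim = range(df$score), ylim = c(0, max(d0$y, d1$y)))
  lines(d1, col = "red")
  abline(v = x$threshold$threshold, lty = 2)
  legend("topright", legend = c("nonbacterial", "any bacterial"),
         col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
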