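# ROC/AUC, sensitivity-anchored threshold derivation, predictive values
# over prevalence, classification and external-cohort validation.

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' scores above a random negative, with ties counted one half. ROC points
#' are returned at every distinct score (rule: `score >= t` is called
#' positive), plus the two trivial endpoints.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return List of class `roc_curve` with `points` (data frame
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  auc <- auc_rank(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, numeric(1))
  points <- data.frame(threshold = c(Inf, thr, -Inf),
                       fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Negative predictive value at a given prevalence
#'
#' `NPV = Sp (1 - pi) / (Sp (1 - pi) + (1 - Se) pi)`. Returns 1 at
#' `pi = 0`; a zero denominator (`pi = 1` with `Se = 1`) is reported as 0
#' with attribute `undefined = TRUE`.
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param prevalence disease prevalence `pi` in `[0, 1]` (vectorized).
#' @return NPV value(s).
#' @export
npv_at_prevalence <- function(se, sp, prevalence) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            all(prevalence >= 0 & prevalence <= 1))
  num <- sp * (1 - prevalence)
  den <- num + (1 - se) * prevalence
  out <- ifelse(prevalence == 0, 1, ifelse(den == 0, 0, num / den))
  if (any(den == 0 & prevalence > 0)) attr(out, "undefined") <- TRUE
  out
}

#' Positive predictive value at a given prevalence
#'
#' `PPV = Se pi / (Se pi + (1 - Sp)(1 - pi))`. Returns 1 at `pi = 1`; a
#' zero denominator is reported as 0 with attribute `undefined = TRUE`.
#'
#' @inheritParams npv_at_prevalence
#' @return PPV value(s).
#' @export
ppv_at_prevalence <- function(se, sp, prevalence) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            all(prevalence >= 0 & prevalence <= 1))
  num <- se * prevalence
  den <- num + (1 - sp) * (1 - prevalence)
  out <- ifelse(prevalence == 1, 1, ifelse(den == 0, 0, num / den))
  if (any(den == 0 & prevalence < 1)) attr(out, "undefined") <- TRUE
  out
}

#' Sensitivity-anchored classification threshold
#'
#' Under the rule "score >= t is called bacterial", returns the largest
#' threshold whose sensitivity is at least `target_se` — which, since
#' specificity is non-decreasing in `t`, simultaneously maximizes
#' specificity subject to the sensitivity floor. Reports the achieved
#' sensitivity/specificity, the confusion counts, and NPV/PPV over a
#' prevalence grid.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = bacterial / positive).
#' @param target_se sensitivity floor in `(0, 1]` (default 0.90).
#' @param prevalence prevalence grid for NPV/PPV (default 0.05 to 0.50 in
#'   steps of 0.05, covering planning prevalences up to 40% and beyond).
#' @return Object of class `threshold_report`: `threshold`, `sensitivity`,
#'   `specificity`, `confusion` (TP, FP, TN, FN), `predictive_values`
#'   (data frame over the prevalence grid), `target_se`, `rule`.
#' @export
threshold_for_sensitivity <- function(scores, labels, target_se = 0.90,
                                      prevalence = seq(0.05, 0.50, by = 0.05)) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1),
            target_se > 0, target_se <= 1)
  pos <- scores[labels == 1L]
  if (length(pos) == 0L) stop("no positive samples; target sensitivity unachievable")
  if (sum(labels == 0L) == 0L) stop("both classes must be present")
  # k-th largest positive score is the largest t with Se(t) >= target
  k <- ceiling(target_se * length(pos))
  t <- sort(pos, decreasing = TRUE)[k]
  classify_at(scores, labels, t, target_se, prevalence)
}

classify_at <- function(scores, labels, t, target_se = NA_real_,
                        prevalence = seq(0.05, 0.50, by = 0.05)) {
  call_pos <- scores >= t
  tp <- sum(call_pos & labels == 1L)
  fp <- sum(call_pos & labels == 0L)
  tn <- sum(!call_pos & labels == 0L)
  fn <- sum(!call_pos & labels == 1L)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  pv <- data.frame(prevalence = prevalence,
                   npv = as.numeric(npv_at_prevalence(se, sp, prevalence)),
                   ppv = as.numeric(ppv_at_prevalence(se, sp, prevalence)))
  structure(list(threshold = t, sensitivity = se, specificity = sp,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 predictive_values = pv, target_se = target_se,
                 rule = sprintf("score >= %.4g => bacterial", t)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, digits = 3, ...) {
  cat("Classification threshold report\n")
  if (!is.na(x$target_se)) {
    cat(sprintf("  target sensitivity: >= %.0f%%\n", 100 * x$target_se))
  }
  cat(sprintf("  rule: %s\n", x$rule))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  rng <- range(x$predictive_values$npv)
  cat(sprintf("  NPV %.3f-%.3f over prevalence %.0f%%-%.0f%%\n",
              rng[1], rng[2], 100 * min(x$predictive_values$prevalence),
              100 * max(x$predictive_values$prevalence)))
  invisible(x)
}

#' Classify samples at a fixed threshold
#'
#' Applies the rule "score >= t is called bacterial". With labels, the
#' confusion table and achieved sensitivity/specificity are reported;
#' without labels (e.g. non-infected controls) only class fractions are.
#'
#' @param scores numeric scores.
#' @param threshold finite classification threshold.
#' @param labels optional binary truth.
#' @return List with `call` (character vector `"bacterial"` /
#'   `"nonbacterial"`), `fraction_bacterial`, and — when labels are given —
#'   a `threshold_report`.
#' @export
classify_scores <- function(scores, threshold, labels = NULL) {
  stopifnot(is.finite(threshold))
  call <- ifelse(scores >= threshold, "bacterial", "nonbacterial")
  out <- list(call = setNames(call, names(scores)),
              fraction_bacterial = mean(call == "bacterial"))
  if (!is.null(labels)) {
    out$report <- classify_at(scores, as.integer(labels), threshold)
  }
  out
}

#' Score and evaluate an external validation cohort
#'
#' Applies a fitted signature to an independently processed cohort and
#' reports the AUC under both transform conventions: `carried` (the
#' training centering/scaling constants are applied unchanged, exactly as
#' coefficients would be deployed) and `refit` (centering/scaling refit on
#' the external cohort, absorbing global processing shifts). Both are
#' reported because independently processed data leave the rescaling
#' convention genuinely ambiguous.
#'
#' @param model a `signature_model`.
#' @param expr gene-by-sample matrix tagged `"cpm"` for the external
#'   cohort.
#' @param labels binary outcome per external sample (`NA` dropped).
#' @return List of class `external_validation`: per-mode `auc`, `scores`,
#'   and `n` used.
#' @export
evaluate_external <- function(model, expr, labels) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) {
    stop("model genes absent from external cohort: ",
         paste(missing, collapse = ", "))
  }
  keep <- !is.na(labels)
  y <- as.integer(labels[keep])
  sc_carried <- predict(model, set_unit(expr[, keep, drop = FALSE], "cpm"))
  # refit mode: re-center/scale the model genes on the external cohort
  l2 <- log2(expr[model$genes, keep, drop = FALSE] + 1)
  ctr <- rowMeans(l2)
  scl <- pmax(apply(l2, 1, sd), 1e-8)
  x <- t((l2 - ctr) / scl)
  sc_refit <- as.numeric(model$intercept + x %*% model$coefficients)
  structure(list(
    auc = c(carried = auc_rank(sc_carried, y), refit = auc_rank(sc_refit, y)),
    scores = data.frame(sample_id = colnames(expr)[keep],
                        score_carried = as.numeric(sc_carried),
                        score_refit = sc_refit, label = y,
                        stringsAsFactors = FALSE),
    n = sum(keep)), class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("External validation (n = %d)\n", x$n))
  cat(sprintf("  AUC (transform carried over): %.3f\n", x$auc["carried"]))
  cat(sprintf("  AUC (transform refit on cohort): %.3f\n", x$auc["refit"]))
  invisible(x)
}
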