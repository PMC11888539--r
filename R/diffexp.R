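# Simplified negative-binomial Wald differential expression:
# median-of-ratios size factors, method-of-moments dispersions shrunk to a
# mean-dispersion trend, two-group NB Wald test, BH adjustment, and the
# leave-one-batch-out consistency analysis.

#' Median-of-ratios size factors
#'
#' Per sample, the size factor is the median over all-nonzero genes of
#' `count / geometric-mean-across-samples`, rescaled so the factors have
#' geometric mean one. If no gene is nonzero in every sample, falls back
#' to total-count ratios with a warning.
#'
#' @param counts gene-by-sample count matrix.
#' @return Positive numeric vector, one factor per sample, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- validate_counts(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no gene with nonzero counts in all samples; falling back to total-count ratios")
    sf <- colSums(counts)
  } else {
    lg <- log(counts[allpos, , drop = FALSE])
    gm <- rowMeans(lg)
    sf <- apply(exp(lg - gm), 2, median)
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments NB dispersions with trend shrinkage
#'
#' Per gene, computes within-class moment estimates
#' `alpha = (s^2 - mean) / mean^2` on size-factor-normalized counts,
#' pools them across the two classes weighted by degrees of freedom,
#' floors at zero, then shrinks on the log scale toward a fitted
#' mean-dispersion trend `a0 + a1 / mean` with a fixed weight.
#'
#' @param counts gene-by-sample count matrix.
#' @param sf size factors from [estimate_size_factors()].
#' @param labels binary class label per sample (0/1); samples with `NA`
#'   are ignored.
#' @param shrink_weight weight on the trend in the log-scale blend
#'   (default 0.5).
#' @param floor minimum dispersion (default 1e-8).
#' @return Numeric vector of per-gene dispersions with attribute
#'   `"raw"` (unshrunk moment estimates) and `"trend"`.
#' @export
estimate_dispersions <- function(counts, sf, labels, shrink_weight = 0.5,
                                 floor = 1e-8) {
  counts <- validate_counts(counts)
  use <- !is.na(labels)
  k <- sweep(counts[, use, drop = FALSE], 2, sf[use], "/")
  y <- as.integer(labels[use])
  raw <- rep(0, nrow(counts))
  wsum <- 0
  for (cl in c(0L, 1L)) {
    ki <- k[, y == cl, drop = FALSE]
    n <- ncol(ki)
    if (n < 2) next
    m <- rowMeans(ki)
    v <- rowSums((ki - m)^2) / (n - 1)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    raw <- raw + (n - 1) * a
    wsum <- wsum + (n - 1)
  }
  if (wsum == 0) stop("need at least 2 samples in some class to estimate dispersion")
  raw <- pmax(raw / wsum, 0)
  mu <- rowMeans(k)
  # parametric trend alpha(mu) = a0 + a1/mu fitted on positive raw estimates
  ok <- raw > floor & mu > 0
  if (sum(ok) >= 10) {
    fit <- tryCatch(
      stats::lm.fit(cbind(1, 1 / mu[ok]), raw[ok])$coefficients,
      error = function(e) c(NA_real_, NA_real_))
    a0 <- fit[1]; a1 <- fit[2]
    # constrain the trend to non-negative components coherently
    if (!all(is.finite(fit)) || a1 < 0) {
      a1 <- 0
      a0 <- mean(raw[ok])
    } else if (a0 < 1e-4) {
      a0 <- 1e-4
      a1 <- max(mean((raw[ok] - a0) * mu[ok]), 0)
    }
    a0 <- max(a0, 1e-4)
  } else {
    a0 <- max(mean(raw[ok]), 1e-4, na.rm = TRUE); a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  disp <- exp((1 - shrink_weight) * log(pmax(raw, floor)) +
                shrink_weight * log(trend))
  disp <- pmax(disp, floor)
  names(disp) <- rownames(counts)
  attr(disp, "raw") <- raw
  attr(disp, "trend") <- trend
  disp
}

#' Two-group negative-binomial Wald test
#'
#' For each gene, estimates the two group means on normalized counts,
#' forms `log2FC = log2((m1 + c)/(m0 + c))` with a half-count pseudocount
#' guard, derives the standard error by the delta method from the NB
#' variance `mu + alpha * mu^2` (accounting for per-sample size factors),
#' and reports the two-sided normal tail probability of the Wald
#' statistic, BH-adjusted across genes. Genes with zero counts in both
#' groups get `log2FC = 0`, `p = 1` and are flagged.
#'
#' @param counts gene-by-sample count matrix.
#' @param labels binary vector (1 = any bacterial, 0 = nonbacterial); `NA`
#'   samples are dropped.
#' @param sf optional size factors (estimated if missing).
#' @param disp optional per-gene dispersions (estimated if missing).
#' @param pseudocount added to both group means inside the log ratio.
#' @return `data.frame` of class `de_result`: `gene`, `baseMean`,
#'   `log2FC`, `se`, `wald`, `p`, `q`, `all_zero`.
#' @export
nb_wald_test <- function(counts, labels, sf = NULL, disp = NULL,
                         pseudocount = 0.5) {
  counts <- validate_counts(counts)
  use <- !is.na(labels)
  counts <- counts[, use, drop = FALSE]
  y <- as.integer(labels[use])
  if (!all(c(0L, 1L) %in% y)) stop("both classes must be non-empty")
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  else sf <- sf[use]
  if (is.null(disp)) disp <- estimate_dispersions(counts, sf, y)
  k <- sweep(counts, 2, sf, "/")

  grp_stats <- function(cl) {
    idx <- y == cl
    ki <- k[, idx, drop = FALSE]
    m <- rowMeans(ki)
    n <- sum(idx)
    # Var(K_i/sf_i) = mu/sf_i + alpha*mu^2 under NB with mean sf_i*mu
    vmean <- (m * sum(1 / sf[idx]) + disp * m^2 * n) / n^2
    list(m = m, vmean = vmean, n = n)
  }
  g0 <- grp_stats(0L)
  g1 <- grp_stats(1L)
  c0 <- pseudocount
  log2fc <- log2((g1$m + c0) / (g0$m + c0))
  ln2sq <- log(2)^2
  v <- g1$vmean / ((g1$m + c0)^2 * ln2sq) + g0$vmean / ((g0$m + c0)^2 * ln2sq)
  se <- sqrt(v)
  all_zero <- g0$m == 0 & g1$m == 0
  wald <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(wald))
  log2fc[all_zero] <- 0
  wald[all_zero] <- 0
  p[all_zero] <- 1
  se[all_zero] <- NA_real_
  res <- data.frame(gene = rownames(counts),
                    baseMean = rowMeans(k),
                    log2FC = log2fc, se = se, wald = wald, p = p,
                    q = bh_adjust(p), all_zero = all_zero,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} p(j) * m / j` on the sorted p-values, mapped back
#' to the input order and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, cummin(rev(p[o] * m / seq_len(m)))[m:1])
  out <- numeric(m)
  out[o] <- q
  out
}

#' Leave-one-batch-out differential-expression consistency
#'
#' Runs the NB-Wald test on the full data at the given FDR, then re-runs
#' it leaving out each batch in turn. The core set is the full-data
#' significant genes that remain significant in every leave-one-batch-out
#' run; the consistency fraction is `|core| / |full-data significant|`.
#' Folds whose removal empties a class are skipped with a warning.
#'
#' @param counts gene-by-sample count matrix.
#' @param annotation data frame with `sample_id`, `batch`, `class`.
#' @param fdr FDR threshold (default 0.05).
#' @return List of class `lobo_de`: `core_genes`, `consistency_fraction`
#'   (`NA` when no gene is significant on the full data), `n_significant`,
#'   `per_fold` (data frame of batch, n significant, n of full-data set
#'   retained), `fdr`.
#' @export
lobo_de_consistency <- function(counts, annotation, fdr = 0.05) {
  counts <- validate_counts(counts)
  y <- outcome_labels(annotation)
  batches <- as.character(annotation$batch)
  ub <- unique(batches[!is.na(y)])
  if (length(ub) < 2) stop("need at least 2 batches")
  full <- nb_wald_test(counts, y)
  sig_full <- full$gene[full$q < fdr]
  per_fold <- data.frame(batch = character(0), n_significant = integer(0),
                         n_core_retained = integer(0), stringsAsFactors = FALSE)
  core <- sig_full
  for (b in ub) {
    keep <- batches != b
    yk <- y[keep]
    if (!all(c(0L, 1L) %in% yk[!is.na(yk)])) {
      warning(sprintf("leaving out batch '%s' empties a class; fold skipped", b))
      next
    }
    res <- nb_wald_test(counts[, keep, drop = FALSE], yk)
    sig_b <- res$gene[res$q < fdr]
    core <- intersect(core, sig_b)
    per_fold <- rbind(per_fold, data.frame(
      batch = b, n_significant = length(sig_b),
      n_core_retained = length(intersect(sig_full, sig_b)),
      stringsAsFactors = FALSE))
  }
  frac <- if (length(sig_full) > 0) length(core) / length(sig_full) else NA_real_
  structure(list(core_genes = core, consistency_fraction = frac,
                 n_significant = length(sig_full), per_fold = per_fold,
                 fdr = fdr),
            class = "lobo_de")
}

#' @export
print.lobo_de <- function(x, ...) {
  cat(sprintf("Leave-one-batch-out DE consistency (FDR < %g)\n", x$fdr))
  cat(sprintf("  full-data significant genes: %d\n", x$n_significant))
  if (is.na(x$consistency_fraction)) {
    cat("  consistency fraction: not applicable (no significant genes)\n")
  } else {
    cat(sprintf("  consistent in all folds: %d (%.0f%%)\n",
                length(x$core_genes), 100 * x$consistency_fraction))
  }
  invisible(x)
}
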