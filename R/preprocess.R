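# QC / filtering cascade: CPM normalisation, low-expression gene filter,
# PCA sample-outlier removal, batch-variance gene filter.

expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("expression matrix carries no unit tag; use compute_cpm()/log2_cpm()")
  u
}

set_unit <- function(x, unit) {
  attr(x, "unit") <- unit
  x
}

#' Counts-per-million normalisation
#'
#' `value(g, s) = counts(g, s) / libsize(s) * 1e6`, where the library size
#' is the column sum. Every column of the result sums to one million.
#'
#' @param counts gene-by-sample matrix of non-negative counts with
#'   dimnames.
#' @return Matrix of the same shape tagged with unit `"cpm"`.
#' @export
compute_cpm <- function(counts) {
  counts <- validate_counts(counts)
  libsize <- colSums(counts)
  zero <- which(libsize == 0)
  if (length(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  set_unit(sweep(counts, 2, libsize, "/") * 1e6, "cpm")
}

#' Log2 CPM with a pseudocount of one
#'
#' @param cpm matrix with unit `"cpm"` (from [compute_cpm()]).
#' @return Matrix of `log2(CPM + 1)` tagged with unit `"log2cpm"`.
#' @export
log2_cpm <- function(cpm) {
  if (expr_unit(cpm) != "cpm") stop("log2_cpm() expects a cpm-scale matrix")
  set_unit(log2(cpm + 1), "log2cpm")
}

#' Filter genes with insufficient expression
#'
#' A gene is retained iff its mean CPM across samples is at least
#' `threshold`; strictly smaller means are removed (the boundary value is
#' kept). The default threshold of 2 CPM reflects standard practice for
#' whole-blood bulk RNA-seq.
#'
#' @param cpm matrix with unit `"cpm"`.
#' @param threshold minimum mean CPM; must be positive.
#' @return Logical vector aligned with the gene order, `TRUE` = keep.
#' @export
filter_genes_by_mean_cpm <- function(cpm, threshold = 2) {
  if (expr_unit(cpm) != "cpm") {
    stop("filter_genes_by_mean_cpm() expects a cpm-scale matrix (scale tag mismatch)")
  }
  if (threshold < 0) stop("threshold must be non-negative")
  keep <- rowMeans(cpm) >= threshold
  names(keep) <- rownames(cpm)
  keep
}

#' Detect outlier samples by robust PCA score screening
#'
#' Performs PCA on gene-centered log2-CPM values and flags a sample as an
#' outlier iff any of its scores on the first `n_components` principal
#' components lies more than `sd_multiplier` robust standard deviations
#' (MAD-scaled) from the component median. Deterministic given the input.
#'
#' @param log2cpm matrix with unit `"log2cpm"`.
#' @param n_components number of leading components screened (default 2).
#' @param sd_multiplier robust-SD multiplier (default 6).
#' @return Logical vector over samples, `TRUE` = outlier.
#' @export
detect_outlier_samples_pca <- function(log2cpm, n_components = 2, sd_multiplier = 6) {
  if (expr_unit(log2cpm) != "log2cpm") {
    stop("detect_outlier_samples_pca() expects a log2cpm-scale matrix")
  }
  n <- ncol(log2cpm)
  if (n < 3) stop("need at least 3 samples for PCA outlier screening")
  if (n_components > min(nrow(log2cpm), n - 1)) {
    stop("n_components exceeds min(genes, samples - 1)")
  }
  centered <- log2cpm - rowMeans(log2cpm)
  pc <- prcomp(t(centered), center = FALSE, scale. = FALSE, rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- rep(FALSE, n)
  for (k in seq_len(n_components)) {
    s <- scores[, k]
    ctr <- median(s)
    sc <- mad(s)
    if (sc < .Machine$double.eps) sc <- sd(s) + .Machine$double.eps
    out <- out | (abs(s - ctr) > sd_multiplier * sc)
  }
  names(out) <- colnames(log2cpm)
  out
}

#' Filter genes dominated by between-batch variance
#'
#' For every gene, decomposes the variance of log2-CPM values into
#' between-batch and within-batch components (one-way layout, sums of
#' squares) and removes genes whose between-batch fraction
#' `SSB / (SSB + SSW)` exceeds `max_batch_fraction`. Batches with fewer
#' than two samples are excluded from the estimate with a warning.
#'
#' @param log2cpm matrix with unit `"log2cpm"`.
#' @param batches batch label per sample.
#' @param max_batch_fraction maximum tolerated between-batch variance
#'   fraction (default 0.5).
#' @return Logical keep-vector over genes with attribute `"components"`, a
#'   data frame of per-gene between/within sums of squares and the batch
#'   fraction.
#' @export
filter_genes_by_batch_variance <- function(log2cpm, batches, max_batch_fraction = 0.5) {
  if (expr_unit(log2cpm) != "log2cpm") {
    stop("filter_genes_by_batch_variance() expects a log2cpm-scale matrix")
  }
  if (length(batches) != ncol(log2cpm)) stop("one batch label per sample required")
  batches <- as.character(batches)
  tab <- table(batches)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("batch(es) with < 2 samples excluded from variance estimate: ",
            paste(small, collapse = ", "))
  }
  use <- batches %in% names(tab)[tab >= 2]
  keep <- rep(TRUE, nrow(log2cpm))
  names(keep) <- rownames(log2cpm)
  comp <- data.frame(gene = rownames(log2cpm), ss_between = 0, ss_within = 0,
                     batch_fraction = 0, stringsAsFactors = FALSE)
  ub <- unique(batches[use])
  if (length(ub) < 2) {
    warning("fewer than 2 usable batches; batch-variance filter is vacuous")
    attr(keep, "components") <- comp
    return(keep)
  }
  x <- log2cpm[, use, drop = FALSE]
  b <- batches[use]
  grand <- rowMeans(x)
  ssb <- rep(0, nrow(x))
  ssw <- rep(0, nrow(x))
  for (bb in ub) {
    xi <- x[, b == bb, drop = FALSE]
    m <- rowMeans(xi)
    ssb <- ssb + ncol(xi) * (m - grand)^2
    ssw <- ssw + rowSums((xi - m)^2)
  }
  tot <- ssb + ssw
  frac <- ifelse(tot > 0, ssb / tot, 0)
  keep[] <- frac <= max_batch_fraction
  comp$ss_between <- ssb
  comp$ss_within <- ssw
  comp$batch_fraction <- frac
  attr(keep, "components") <- comp
  keep
}

#' Run the full QC / filtering cascade
#'
#' Applies, in order: (1) mean-CPM gene filter on CPM computed from all
#' samples; (2) PCA sample-outlier removal on log2 CPM of the retained
#' genes; (3) CPM recomputation on the retained samples (library
#' composition changes once samples are dropped); (4) batch-variance gene
#' filter. Returns the filtered counts together with a reconciling report.
#'
#' @param counts gene-by-sample count matrix.
#' @param annotation data frame with `sample_id`, `batch`, `class` rows
#'   matching the count columns.
#' @param min_cpm mean-CPM threshold (default 2).
#' @param pca_components,pca_sd_multiplier outlier-screen settings.
#' @param max_batch_fraction between-batch variance cutoff.
#' @return List of class `filter_result`: `counts` (filtered), `annotation`
#'   (filtered rows), `cpm`, `log2cpm` (filtered, recomputed), and
#'   `report` — a `filter_report` recording removed genes/samples per rule
#'   and retained dimensions.
#' @export
preprocess_counts <- function(counts, annotation,
                              min_cpm = 2,
                              pca_components = 2,
                              pca_sd_multiplier = 6,
                              max_batch_fraction = 0.5) {
  counts <- validate_counts(counts)
  stopifnot(is.data.frame(annotation),
            all(c("sample_id", "batch", "class") %in% names(annotation)))
  if (!identical(colnames(counts), as.character(annotation$sample_id))) {
    stop("annotation sample_id must match count matrix columns in order")
  }
  cpm0 <- compute_cpm(counts)
  keep_expr <- filter_genes_by_mean_cpm(cpm0, min_cpm)
  removed_low <- rownames(counts)[!keep_expr]

  c1 <- counts[keep_expr, , drop = FALSE]
  out <- detect_outlier_samples_pca(log2_cpm(compute_cpm(c1)),
                                    n_components = pca_components,
                                    sd_multiplier = pca_sd_multiplier)
  removed_samples <- colnames(c1)[out]

  c2 <- c1[, !out, drop = FALSE]
  ann2 <- annotation[!out, , drop = FALSE]
  cpm2 <- compute_cpm(c2)
  l2 <- log2_cpm(cpm2)
  keep_batch <- filter_genes_by_batch_variance(l2, ann2$batch, max_batch_fraction)
  removed_batchvar <- rownames(c2)[!keep_batch]

  c3 <- c2[keep_batch, , drop = FALSE]
  report <- structure(list(
    genes_removed_low_expression = removed_low,
    samples_removed_pca = removed_samples,
    genes_removed_batch_variance = removed_batchvar,
    n_genes_in = nrow(counts), n_samples_in = ncol(counts),
    n_genes_retained = nrow(c3), n_samples_retained = ncol(c3),
    settings = list(min_cpm = min_cpm, pca_components = pca_components,
                    pca_sd_multiplier = pca_sd_multiplier,
                    max_batch_fraction = max_batch_fraction)
  ), class = "filter_report")

  structure(list(counts = c3, annotation = ann2,
                 cpm = compute_cpm(c3), log2cpm = log2_cpm(compute_cpm(c3)),
                 report = report),
            class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter report\n")
  cat(sprintf("  input:    %d genes x %d samples\n", x$n_genes_in, x$n_samples_in))
  cat(sprintf("  mean-CPM < %g:        removed %d genes\n",
              x$settings$min_cpm, length(x$genes_removed_low_expression)))
  cat(sprintf("  PCA outliers (%d PC, %g robust SD): removed %d samples\n",
              x$settings$pca_components, x$settings$pca_sd_multiplier,
              length(x$samples_removed_pca)))
  cat(sprintf("  batch-variance fraction > %g: removed %d genes\n",
              x$settings$max_batch_fraction,
              length(x$genes_removed_batch_variance)))
  cat(sprintf("  retained: %d genes x %d samples\n",
              x$n_genes_retained, x$n_samples_retained))
  invisible(x)
}

# Shared count-matrix validation: numeric matrix, whole non-negative
# entries, unique dimnames.
validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample id(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  counts
}
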