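mk_counts <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

test_that("CPM normalisation is exact arithmetic and always sums to one million", {
  counts <- mk_counts(matrix(c(10, 90), 2, 1))
  cpm <- compute_cpm(counts)
  expect_equal(as.numeric(cpm), c(1e5, 9e5))

  counts <- mk_counts(rbind(matrix(5, 3, 4), 0))
  expect_equal(unname(compute_cpm(counts)[4, ]), rep(0, 4))

  set.seed(1)
  counts <- mk_counts(matrix(rpois(50 * 20, 30), 50, 20))
  cpm <- compute_cpm(counts)
  expect_equal(unname(colSums(cpm)), rep(1e6, 20))
  expect_identical(attr(cpm, "unit"), "cpm")
})

test_that("CPM is invariant to rescaling one sample's counts", {
  set.seed(2)
  counts <- mk_counts(matrix(rpois(200, 40), 20, 10))
  cpm <- compute_cpm(counts)
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 7
  expect_equal(compute_cpm(counts2)[, 3], cpm[, 3])
})

test_that("zero library sizes are rejected naming the sample", {
  counts <- mk_counts(matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(compute_cpm(counts), "s2")
})

test_that("the mean-CPM filter removes strictly below threshold and keeps the boundary", {
  # single sample with library size 1e8: CPM = count / 100
  counts <- mk_counts(matrix(c(199, 200, 99999601), 3, 1),
                      genes = c("below", "boundary", "big"))
  cpm <- compute_cpm(counts)
  expect_equal(unname(cpm[1:2, 1]), c(1.99, 2.00))
  keep <- filter_genes_by_mean_cpm(cpm, 2)
  expect_false(keep[["below"]])
  expect_true(keep[["boundary"]])
  expect_true(all(filter_genes_by_mean_cpm(cpm, 0)))
  expect_error(filter_genes_by_mean_cpm(log2_cpm(cpm), 2), "scale tag|cpm-scale")
})

test_that("PCA screening flags planted outliers and spares duplicates", {
  sim <- small_cohort(seed = 3, n_genes = 300)
  l2 <- log2_cpm(compute_cpm(sim$counts))
  shifted <- l2
  shifted[, 5] <- shifted[, 5] + 8
  attr(shifted, "unit") <- "log2cpm"
  flags <- detect_outlier_samples_pca(shifted)
  expect_true(flags[5])
  expect_equal(sum(flags), 1L)

  # a duplicated sample is no more unusual than its twin: on a matrix with
  # dominant low-rank structure (as real expression data have) neither is
  # flagged
  set.seed(31)
  fac <- matrix(rnorm(40 * 2), 2, 40)
  load <- matrix(rnorm(300 * 2, 0, 2), 300, 2)
  smooth <- load %*% fac + matrix(rnorm(300 * 40, 0, 0.3), 300, 40)
  dimnames(smooth) <- list(sprintf("g%d", 1:300), sprintf("s%d", 1:40))
  dup <- cbind(smooth, dup = smooth[, 1])
  attr(dup, "unit") <- "log2cpm"
  flags_dup <- detect_outlier_samples_pca(dup)
  expect_identical(flags_dup[["dup"]], flags_dup[["s1"]])
  expect_false(flags_dup[["dup"]])

  expect_error(detect_outlier_samples_pca(l2, n_components = 1000), "n_components")
  expect_error(detect_outlier_samples_pca(compute_cpm(sim$counts)), "log2cpm")
})

test_that("a homogeneous cohort yields no PCA outliers at the default multiplier", {
  flagged <- vapply(1:5, function(s) {
    sim <- null_cohort(seed = s, n_genes = 300)
    sum(detect_outlier_samples_pca(log2_cpm(compute_cpm(sim$counts))))
  }, numeric(1))
  expect_gte(mean(flagged == 0), 0.8)
})

test_that("planted compositional outliers are recovered at default settings", {
  hits <- vapply(1:10, function(s) {
    sim <- small_cohort(seed = s, n_genes = 400,
                        n = c(V = 60, B = 30, VB = 20, NI = 10))
    set.seed(s + 500)
    out_idx <- sample(ncol(sim$counts), 11)
    gsub <- sample(nrow(sim$counts), nrow(sim$counts) %/% 2)
    counts <- sim$counts
    counts[gsub, out_idx] <- counts[gsub, out_idx] * 2^6
    flags <- detect_outlier_samples_pca(log2_cpm(compute_cpm(counts)))
    sum(which(flags) %in% out_idx)
  }, numeric(1))
  expect_gte(mean(hits >= 10), 0.9)
})

test_that("batch-variance filtering removes batch-dominated genes only", {
  set.seed(4)
  n_per <- 10
  batches <- rep(1:3, each = n_per)
  x <- matrix(rnorm(5 * 30, 5, 0.1), 5, 30)
  x[1, ] <- 5 + 4 * (batches - 2) + rnorm(30, 0, 0.05)  # batch-driven gene
  x[2, ] <- 7                                            # constant gene
  x <- mk_counts(x)
  attr(x, "unit") <- "log2cpm"
  keep <- filter_genes_by_batch_variance(x, batches, max_batch_fraction = 0.5)
  expect_false(keep[["g1"]])
  expect_true(keep[["g2"]])
  comp <- attr(keep, "components")
  expect_equal(comp$ss_between[2], 0)
  expect_gt(comp$batch_fraction[1], 0.9)

  expect_warning(k1 <- filter_genes_by_batch_variance(x, rep(1, 30)), "vacuous|batches")
  expect_true(all(k1))
  expect_warning(expect_warning(
    filter_genes_by_batch_variance(x, c(rep(1, 29), 2)), "< 2 samples"),
    "fewer than 2 usable")
})

test_that("the filter cascade reconciles exactly", {
  sim <- small_cohort(seed = 9, n_genes = 400)
  res <- preprocess_counts(sim$counts, sim$annotation)
  rep <- res$report
  expect_equal(rep$n_genes_in - length(rep$genes_removed_low_expression) -
                 length(rep$genes_removed_batch_variance), rep$n_genes_retained)
  expect_equal(rep$n_samples_in - length(rep$samples_removed_pca),
               rep$n_samples_retained)
  expect_equal(dim(res$counts), c(rep$n_genes_retained, rep$n_samples_retained))
  expect_identical(colnames(res$counts), res$annotation$sample_id)
  # removed and retained sets are disjoint
  expect_length(intersect(rownames(res$counts),
                          c(rep$genes_removed_low_expression,
                            rep$genes_removed_batch_variance)), 0)
  expect_output(print(rep), "QC filter report")
})

test_that("count validation catches duplicates and non-integers", {
  m <- mk_counts(matrix(1:4, 2, 2), genes = c("a", "a"))
  expect_error(preprocess_counts(m, data.frame()), "duplicate gene")
  m2 <- mk_counts(matrix(c(1, 2.5, 3, 4), 2, 2))
  expect_error(compute_cpm(m2), "non-integer count at gene 'g2', sample 's1'")
})
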