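mk <- function(m) {
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  m
}

test_that("median-of-ratios size factors satisfy their exact identities", {
  set.seed(1)
  base <- matrix(rpois(200, 50) + 1, 20, 10)
  doubled <- mk(cbind(base[, 1], base[, 1] * 2))
  sf <- estimate_size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  same <- mk(base[, c(1, 1, 1)])
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))

  # invariance to a global constant
  m <- mk(base)
  expect_equal(estimate_size_factors(m * 5), estimate_size_factors(m))

  # fallback when no gene is positive everywhere
  m0 <- mk(rbind(c(0, 5), c(5, 0)))
  expect_warning(sf0 <- estimate_size_factors(m0), "total-count")
  expect_equal(unname(sf0), c(1, 1))
})

test_that("size factors agree with DESeq2's median-of-ratios up to a constant", {
  set.seed(2)
  m <- mk(matrix(rnbinom(300 * 12, mu = 80, size = 4), 300, 12))
  m <- round(sweep(m, 2, runif(12, 0.5, 2), "*"))
  sf <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # conventions differ only in how an even number of ratios is averaged
  expect_equal(unname(sf / sf[1]), unname(ref / ref[1]), tolerance = 1e-4)
})

test_that("size factors recover simulated library-size factors", {
  sim <- null_cohort(seed = 4, n_genes = 2000,
                     n = c(V = 25, B = 13, VB = 8, NI = 0), n_batches = 2,
                     batch_effect_sd = 0)
  sf <- estimate_size_factors(sim$counts)
  rel <- sf / sim$truth$libsize_factor - 1
  expect_lt(median(abs(rel)), 0.03)
  expect_lt(max(abs(rel)), 0.1)
})

test_that("moment dispersion estimation recovers truth and handles limit cases", {
  set.seed(5)
  n <- 500
  labels <- rep(0:1, each = n / 2)
  nb <- matrix(rnbinom(50 * n, size = 1 / 0.5, mu = 200), 50, n)
  pois <- matrix(rpois(10 * n, 150), 10, n)
  cons <- matrix(7, 1, n)
  counts <- mk(rbind(nb, pois, cons))
  disp <- estimate_dispersions(counts, rep(1, n), labels)
  expect_lt(max(abs(disp[1:50] / 0.5 - 1)), 0.2)
  expect_lt(max(disp[51:60]), 0.05)
  expect_lt(disp[[61]], 1e-3)
  raw <- attr(disp, "raw")
  expect_equal(unname(raw[61]), 0)
})

test_that("BH step-up matches hand computation, brute force and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_bruteforce(p))
    expect_equal(q, p.adjust(p, "BH"))
  }
  # monotone in p-rank and bounded by 1
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1 & q >= p * 0))
  expect_gte(q[which.min(p)], min(p))
})

test_that("the NB Wald test recovers a planted fold change", {
  sim <- simulate_cohort(sim_config(
    n_genes = 500, n_samples_per_class = c(V = 250, B = 250, VB = 0, NI = 0),
    n_batches = 1, batch_effect_sd = 0,
    signature_spec = data.frame(gene = 1, direction = "bacterial", effect = 2),
    n_weak_de_genes = 0, seed = 7))
  de <- nb_wald_test(sim$counts, outcome_labels(sim$annotation))
  expect_lt(abs(de$log2FC[1] - 2), 0.3)
  expect_lt(de$q[1], 1e-6)
  # internal consistency of the Wald statistic
  ok <- !de$all_zero & de$se > 0
  expect_equal(de$wald[ok] * de$se[ok], de$log2FC[ok], tolerance = 1e-12)
})

test_that("the NB Wald test is antisymmetric in the group labels", {
  sim <- null_cohort(seed = 8, n_genes = 200)
  y <- outcome_labels(sim$annotation)
  d1 <- nb_wald_test(sim$counts, y)
  d2 <- nb_wald_test(sim$counts, 1L - y)
  expect_equal(d2$log2FC, -d1$log2FC, tolerance = 1e-10)
  expect_equal(d2$wald, -d1$wald, tolerance = 1e-10)
  expect_equal(d2$p, d1$p, tolerance = 1e-10)
})

test_that("degenerate genes are handled: all-zero flagged, constant genes null", {
  set.seed(9)
  m <- mk(rbind(matrix(rpois(4 * 40, 60), 4, 40), 0, 5))
  y <- rep(0:1, 20)
  de <- nb_wald_test(m, y, sf = rep(1, 40))
  expect_true(de$all_zero[5])
  expect_equal(de$p[5], 1)
  expect_equal(de$log2FC[5], 0)
  # constant gene: identical group means by construction
  expect_equal(de$wald[6], 0, tolerance = 1e-8)
  expect_gt(de$p[6], 0.99)
})

test_that("permuted labels give nominal type-I error", {
  sim <- small_cohort(seed = 10, n_genes = 800,
                      n = c(V = 80, B = 40, VB = 25, NI = 0))
  y <- outcome_labels(sim$annotation)
  set.seed(11)
  rej <- mean(nb_wald_test(sim$counts, sample(y))$p < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("LOBO DE consistency handles strong signal and degenerate designs", {
  sim <- simulate_cohort(sim_config(
    n_genes = 600, n_samples_per_class = c(V = 70, B = 35, VB = 25, NI = 0),
    n_batches = 4, batch_effect_sd = 0, n_weak_de_genes = 120,
    weak_effect = list(meanlog = log(1.4), sdlog = 0.25), seed = 12))
  res <- lobo_de_consistency(sim$counts, sim$annotation)
  expect_gt(res$consistency_fraction, 0.8)
  expect_true(all(res$core_genes %in%
                    rownames(sim$counts)[sim$truth$de_status]))
  expect_equal(nrow(res$per_fold), 4L)

  # fdr = 0 (well, numerically zero-equivalent) -> empty set, NA fraction
  res0 <- lobo_de_consistency(sim$counts, sim$annotation, fdr = 1e-300)
  expect_true(is.na(res0$consistency_fraction))
  expect_output(print(res0), "not applicable")

  # one batch carrying all of one class -> fold skipped with warning
  ann <- sim$annotation
  ann$batch[ann$class %in% c("B", "VB")] <- 9
  ann$batch[!ann$class %in% c("B", "VB")] <- rep_len(1:2, sum(!ann$class %in% c("B", "VB")))
  expect_warning(lobo_de_consistency(sim$counts, ann), "empties a class")
})
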