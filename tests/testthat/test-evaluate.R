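test_that("AUC follows the Mann-Whitney convention with ties counted half", {
  expect_equal(roc_auc(c(2, 3, 1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(1)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:5) {
    scores <- rnorm(80)
    labels <- rbinom(80, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC curves start at (0,0), end at (1,1) and are monotone", {
  set.seed(3)
  r <- roc_auc(rnorm(50), rbinom(50, 1, 0.5))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("the sensitivity-anchored threshold matches exhaustive search", {
  rep1 <- threshold_for_sensitivity(c(3, 2, 1, 0), c(1, 1, 1, 0), 0.9)
  expect_equal(rep1$threshold, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)

  # target 1.0 forces the minimum positive score
  rep2 <- threshold_for_sensitivity(c(5, 4, -1, 0), c(1, 1, 1, 0), 1)
  expect_equal(rep2$threshold, -1)

  set.seed(4)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    scores <- round(rnorm(n), sample(1:2, 1))
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    target <- runif(1, 0.5, 1)
    mine <- threshold_for_sensitivity(scores, labels, target)
    expect_equal(mine$threshold, threshold_bruteforce(scores, labels, target))
    expect_gte(mine$sensitivity, target)
  }
})

test_that("threshold reports are consistent with the ROC curve", {
  set.seed(5)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.45)
  roc <- roc_auc(scores, labels)
  rep <- threshold_for_sensitivity(scores, labels, 0.9)
  i <- which(abs(roc$points$tpr - rep$sensitivity) < 1e-12 &
               abs(roc$points$fpr - (1 - rep$specificity)) < 1e-12)
  expect_gte(length(i), 1)
  cm <- rep$confusion
  expect_equal(rep$sensitivity, cm["TP"] / (cm["TP"] + cm["FN"]),
               ignore_attr = TRUE)
  expect_equal(rep$specificity, cm["TN"] / (cm["TN"] + cm["FP"]),
               ignore_attr = TRUE)
})

test_that("predictive values reproduce the analytic identities", {
  expect_equal(round(npv_at_prevalence(0.90, 0.71, 0.40), 2), 0.91)
  expect_gt(npv_at_prevalence(0.90, 0.71, 0.25), 0.95)
  expect_equal(npv_at_prevalence(1, 0.3, 0.7), 1)
  expect_equal(npv_at_prevalence(0.8, 0.7, 0), 1)
  expect_equal(ppv_at_prevalence(0.8, 0.7, 1), 1)

  # monotonicity over a prevalence grid
  grid <- seq(0, 1, by = 0.05)
  npv <- npv_at_prevalence(0.9, 0.71, grid)
  ppv <- ppv_at_prevalence(0.9, 0.71, grid)
  expect_true(all(diff(as.numeric(npv)) <= 1e-15))
  expect_true(all(diff(as.numeric(ppv)) >= -1e-15))

  und <- npv_at_prevalence(1, 0.5, 1)
  expect_equal(as.numeric(und), 0)
  expect_true(isTRUE(attr(und, "undefined")))
  expect_error(npv_at_prevalence(1.2, 0.5, 0.5))
})

test_that("classification at a fixed threshold behaves at the extremes", {
  scores <- c(a = -2, b = 0, c = 3)
  lo <- classify_scores(scores, -100)
  expect_true(all(lo$call == "bacterial"))
  hi <- classify_scores(scores, 100)
  expect_true(all(hi$call == "nonbacterial"))
  expect_error(classify_scores(scores, Inf), "finite")

  withlab <- classify_scores(scores, 0, labels = c(0, 1, 1))
  expect_equal(unname(withlab$report$confusion),
               c(2L, 0L, 1L, 0L))  # TP FP TN FN
})

test_that("controls drawn from the negative score distribution are called nonbacterial at rate Sp", {
  set.seed(6)
  neg <- rnorm(4000, 0, 1)
  pos <- rnorm(4000, 1.8, 1)
  scores <- c(pos, neg)
  labels <- rep(1:0, each = 4000)
  rep <- threshold_for_sensitivity(scores, labels, 0.9)
  controls <- rnorm(4000, 0, 1)  # same distribution as negatives
  cl <- classify_scores(controls, rep$threshold)
  expect_lt(abs((1 - cl$fraction_bacterial) - rep$specificity), 0.03)
})

test_that("external validation transfers, collapses without signal, and is scale-aware", {
  sim <- small_cohort(seed = 7, n_genes = 300,
                      n = c(V = 70, B = 35, VB = 25, NI = 0))
  y <- outcome_labels(sim$annotation)
  cpm <- compute_cpm(sim$counts)
  model <- fit_signature(cpm, y, sim$annotation$batch, fast_grid())
  train_auc <- roc_auc(predict(model, cpm), y)$auc

  # identity: external set equal to the training set
  same <- evaluate_external(model, cpm, y)
  expect_equal(unname(same$auc["carried"]), train_auc)

  # independently processed cohort with the same planted effects
  val <- simulate_validation_cohort(sim$truth, seed = 11)
  ev <- evaluate_external(model, compute_cpm(val$counts),
                         outcome_labels(val$annotation))
  expect_gt(ev$auc["carried"], train_auc - 0.12)

  # library-size rescaling is absorbed by CPM: identical scores
  scaled <- val$counts * 10
  ev10 <- evaluate_external(model, compute_cpm(scaled),
                           outcome_labels(val$annotation))
  expect_equal(ev10$auc, ev$auc, tolerance = 1e-12)

  # signal-free cohort scores at chance
  v0 <- simulate_validation_cohort(sim$truth, effect_scale = 0, seed = 12)
  ev0 <- evaluate_external(model, compute_cpm(v0$counts),
                          outcome_labels(v0$annotation))
  expect_lt(abs(ev0$auc["carried"] - 0.5), 0.12)

  expect_error(evaluate_external(model, cpm[-match(model$genes[1], rownames(cpm)), ], y),
               model$genes[1])
})
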