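test_that("the expression transform standardizes, round-trips and validates", {
  sim <- small_cohort(seed = 1, n_genes = 200)
  cpm <- compute_cpm(sim$counts)
  tf <- transform_expression(cpm)
  expect_equal(unname(colMeans(tf$x)), rep(0, ncol(tf$x)), tolerance = 1e-12)
  expect_equal(unname(apply(tf$x, 2, sd)), rep(1, ncol(tf$x)), tolerance = 1e-12)

  # scoring mode with the spec fitted on the same matrix is idempotent
  tf2 <- transform_expression(cpm, spec = tf$spec)
  expect_equal(tf2$x, tf$x)

  # a constant gene is floored and maps to all zeros
  cc <- rbind(cpm, const = 5)
  attr(cc, "unit") <- "cpm"
  tfc <- transform_expression(cc)
  expect_equal(unname(tfc$x[, "const"]), rep(0, nrow(tfc$x)))

  spec_bad <- tf$spec
  spec_bad$gene <- c(spec_bad$gene[-1], "NOT_A_GENE")
  expect_error(transform_expression(cpm, spec = spec_bad), "NOT_A_GENE")
})

test_that("tuning grids are validated", {
  expect_error(tuning_grid(lambda = c(0.1, 0.2)), "decreasing")
  expect_error(tuning_grid(gamma = c(-0.1, 0.5)), "gamma")
  expect_error(tuning_grid(gamma = numeric(0)), "gamma")
  expect_error(tuning_grid(tau = -1), "tau")
})

test_that("a single grid point is returned unchanged by the tuner", {
  sim <- small_cohort(seed = 2, n_genes = 200)
  y <- outcome_labels(sim$annotation)
  keep <- !is.na(y)
  tf <- transform_expression(compute_cpm(sim$counts[, keep]))
  tune <- tune_signature_lobo(tf$x, y[keep], sim$annotation$batch[keep],
                              tuning_grid(lambda = 0.05, gamma = 0.1, tau = 0.02))
  expect_equal(tune$lambda, 0.05)
  expect_equal(tune$gamma, 0.1)
  expect_equal(tune$tau, 0.02)
})

test_that("tuning a pure-noise cohort respects the budget and finds no signal", {
  sim <- null_cohort(seed = 3, n_genes = 300)
  y <- outcome_labels(sim$annotation)
  tf <- transform_expression(compute_cpm(sim$counts))
  tune <- tune_signature_lobo(tf$x, y, sim$annotation$batch, fast_grid(),
                              sparsity_budget = 6)
  expect_lte(tune$median_support, 6)
  expect_gt(tune$inner_auc, 0.3)
  expect_lt(tune$inner_auc, 0.7)
})

test_that("nested LOBO cross-validation is leakage-free and complete", {
  sim <- small_cohort(seed = 4, n_genes = 300)
  y <- outcome_labels(sim$annotation)
  cpm <- compute_cpm(sim$counts)
  batches <- sim$annotation$batch
  cv <- cv_signature(cpm, y, batches, fast_grid())
  keep <- !is.na(y)
  # every labeled sample appears in exactly one outer held-out fold
  expect_equal(nrow(cv$scores), sum(keep))
  expect_setequal(cv$scores$sample_id, sim$annotation$sample_id[keep])
  expect_equal(sum(vapply(cv$folds, function(f) length(f$scores), numeric(1))),
               sum(keep))

  # each fold's scorer depends only on its own training batches: refitting
  # from scratch on batches != b reproduces the fold model exactly
  b <- names(cv$folds)[1]
  tr <- keep & batches != b
  tf <- transform_expression(compute_cpm(sim$counts[, tr]))
  tune <- tune_signature_lobo(tf$x, y[tr], batches[tr], fast_grid(), 6)
  model <- bactsig:::fit_at_tuning(tf$x, y[tr], tune)
  expect_equal(setNames(model$beta, colnames(tf$x)[model$support]),
               cv$folds[[b]]$coefficients)

  expect_error(cv_signature(cpm, y, rep(1:2, length.out = length(y)), fast_grid()),
               "at least 3 batches")
})

test_that("the fitted signature is deterministic and recovers planted genes", {
  sim <- small_cohort(seed = 5, n_genes = 400,
                      n = c(V = 70, B = 35, VB = 25, NI = 0))
  y <- outcome_labels(sim$annotation)
  cpm <- compute_cpm(sim$counts)
  m1 <- fit_signature(cpm, y, sim$annotation$batch, fast_grid())
  m2 <- fit_signature(cpm, y, sim$annotation$batch, fast_grid())
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$tuning, m2$tuning)

  planted <- rownames(sim$counts)[sim$truth$signature$gene]
  expect_gte(length(intersect(m1$genes, planted)), 3)
  expect_lte(length(m1$genes), 6)
  # planted directions carry the right signs
  hit <- intersect(m1$genes, planted)
  dirs <- setNames(sim$truth$signature$direction, planted)[hit]
  expect_true(all(sign(m1$coefficients[hit]) ==
                    ifelse(dirs == "bacterial", 1, -1)))
})

test_that("risk scores are a pure function of the model and its genes", {
  sim <- small_cohort(seed = 6, n_genes = 300)
  y <- outcome_labels(sim$annotation)
  cpm <- compute_cpm(sim$counts)
  model <- fit_signature(cpm, y, sim$annotation$batch, fast_grid())
  s1 <- predict(model, cpm)
  # scoring from only the model genes gives identical results
  sub <- cpm[model$genes, , drop = FALSE]
  attr(sub, "unit") <- "cpm"
  expect_equal(predict(model, sub), s1)
  expect_equal(risk_score(model, cpm), s1)
  # linear form check
  x <- transform_expression(sub, spec = model$transform)$x
  expect_equal(unname(s1),
               as.numeric(model$intercept + x %*% model$coefficients))
  expect_error(predict(model, cpm[setdiff(rownames(cpm), model$genes[1]), ] |>
                         (\(m) { attr(m, "unit") <- "cpm"; m })()),
               "absent")
})

test_that("an aggressive threshold on noise yields a usable intercept-only model", {
  sim <- null_cohort(seed = 7, n_genes = 200)
  y <- outcome_labels(sim$annotation)
  cpm <- compute_cpm(sim$counts)
  model <- fit_signature(cpm, y, sim$annotation$batch,
                         tuning_grid(nlambda = 5, gamma = 0, tau = 5))
  expect_length(model$genes, 0)
  sc <- predict(model, cpm)
  expect_equal(unname(sc), rep(model$intercept, ncol(cpm)))
})

test_that("model serialization round-trips through JSON", {
  sim <- small_cohort(seed = 8, n_genes = 250)
  y <- outcome_labels(sim$annotation)
  cpm <- compute_cpm(sim$counts)
  model <- fit_signature(cpm, y, sim$annotation$batch, fast_grid())
  path <- tempfile(fileext = ".json")
  write_signature_model(model, path)
  back <- read_signature_model(path)
  expect_equal(predict(back, cpm), predict(model, cpm), tolerance = 1e-12)
  expect_identical(back$genes, model$genes)
  expect_equal(back$tuning$lambda, model$tuning$lambda)
})
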