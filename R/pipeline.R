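# End-to-end orchestration: simulate (optional) -> QC/filter -> DE with
# LOBO consistency -> nested CV -> final signature -> threshold ->
# external validation, with every artifact written to disk.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with validated defaults. The
#' configuration round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param counts,annotation input paths (TSV/MTX and CSV), or `NULL` to
#'   simulate a cohort instead.
#' @param simulate list of [sim_config()] overrides used when no input
#'   paths are given.
#' @param min_cpm,pca_components,pca_sd_multiplier,max_batch_fraction
#'   QC/filter settings (see [preprocess_counts()]).
#' @param fdr differential-expression FDR threshold.
#' @param nlambda,lambda_min_ratio,gamma,tau tuning-grid settings (see
#'   [tuning_grid()]).
#' @param sparsity_budget maximum median support size during tuning.
#' @param target_sensitivity sensitivity floor for the classification
#'   threshold.
#' @param prevalence prevalence grid for NPV/PPV reporting.
#' @param run_cv whether to run the nested LOBO cross-validation stage.
#' @param validate_external whether to score a simulated external cohort
#'   (only available for simulated inputs).
#' @param seed integer seed for all randomness.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, annotation = NULL,
                            simulate = list(),
                            min_cpm = 2, pca_components = 2,
                            pca_sd_multiplier = 6, max_batch_fraction = 0.5,
                            fdr = 0.05,
                            nlambda = 20, lambda_min_ratio = 0.05,
                            gamma = c(0, 0.1, 0.25, 0.5, 1),
                            tau = c(0, 0.05, 0.1, 0.25),
                            sparsity_budget = 6,
                            target_sensitivity = 0.90,
                            prevalence = seq(0.05, 0.50, by = 0.05),
                            run_cv = TRUE, validate_external = TRUE,
                            seed = 1L) {
  stopifnot(min_cpm >= 0, fdr > 0, fdr < 1,
            target_sensitivity > 0, target_sensitivity <= 1,
            all(prevalence >= 0 & prevalence <= 1),
            sparsity_budget > 0)
  tuning_grid(nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
              gamma = gamma, tau = tau)  # validates grid settings
  cfg <- list(counts = counts, annotation = annotation, simulate = simulate,
              min_cpm = min_cpm, pca_components = pca_components,
              pca_sd_multiplier = pca_sd_multiplier,
              max_batch_fraction = max_batch_fraction, fdr = fdr,
              nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
              gamma = gamma, tau = tau, sparsity_budget = sparsity_budget,
              target_sensitivity = target_sensitivity,
              prevalence = prevalence, run_cv = run_cv,
              validate_external = validate_external, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full signature-derivation pipeline
#'
#' Executes, in order: cohort simulation (when no input paths are
#' configured), QC filtering, differential expression with the
#' leave-one-batch-out consistency analysis, nested LOBO cross-validation,
#' final signature fitting, sensitivity-anchored threshold derivation, and
#' (for simulated inputs) external-cohort validation. Every artifact is
#' written under `out_dir` together with a run manifest recording the
#' configuration, seed, stage timings and package version.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return List of class `pipeline_result` with the in-memory artifacts:
#'   `filtered`, `de`, `lobo_de`, `cv`, `model`, `threshold`, `scores`,
#'   `external`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    t_all[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  truth <- NULL
  if (is.null(config$counts)) {
    sim <- tick("simulate", {
      sc <- do.call(sim_config, modifyList(list(seed = config$seed),
                                           config$simulate))
      simulate_cohort(sc)
    })
    counts <- sim$counts
    annotation <- sim$annotation
    truth <- sim$truth
  } else {
    if (!file.exists(config$counts) ||
        is.null(config$annotation) || !file.exists(config$annotation)) {
      stop("pipeline stage 'input' failed: missing input path(s)")
    }
    counts <- tick("read", read_counts(config$counts))
    annotation <- read_sample_annotation(config$annotation)
  }

  filtered <- tick("preprocess", preprocess_counts(
    counts, annotation, min_cpm = config$min_cpm,
    pca_components = config$pca_components,
    pca_sd_multiplier = config$pca_sd_multiplier,
    max_batch_fraction = config$max_batch_fraction))

  y <- outcome_labels(filtered$annotation)
  de <- tick("de", nb_wald_test(filtered$counts, y))
  lobo <- tick("lobo_de",
               lobo_de_consistency(filtered$counts, filtered$annotation,
                                   fdr = config$fdr))

  grid <- tuning_grid(nlambda = config$nlambda,
                      lambda_min_ratio = config$lambda_min_ratio,
                      gamma = config$gamma, tau = config$tau)
  cpm <- filtered$cpm
  batches <- filtered$annotation$batch
  cv <- NULL
  if (isTRUE(config$run_cv)) {
    cv <- tick("cv", cv_signature(cpm, y, batches, grid,
                                  config$sparsity_budget))
  }
  model <- tick("fit", fit_signature(cpm, y, batches, grid,
                                     config$sparsity_budget))
  labeled <- !is.na(y)
  scores <- predict(model, set_unit(cpm[, labeled, drop = FALSE], "cpm"))
  threshold <- tick("threshold", threshold_for_sensitivity(
    scores, y[labeled], target_se = config$target_sensitivity,
    prevalence = config$prevalence))

  external <- NULL
  if (isTRUE(config$validate_external) && !is.null(truth)) {
    external <- tick("validate", {
      val <- simulate_validation_cohort(truth, seed = config$seed + 1L)
      vcpm <- compute_cpm(val$counts)
      evaluate_external(model, vcpm[model$genes, , drop = FALSE] |>
                          set_unit("cpm"),
                        outcome_labels(val$annotation))
    })
  }

  # artifacts
  write_counts(filtered$counts, file.path(out_dir, "filtered_counts.tsv"))
  write_sample_annotation(filtered$annotation,
                          file.path(out_dir, "filtered_annotation.csv"))
  write_de_table(de, file.path(out_dir, "de_results.tsv"))
  write_signature_model(model, file.path(out_dir, "model.json"))
  score_df <- data.frame(sample_id = names(scores), score = unname(scores),
                         label = y[labeled],
                         call = ifelse(scores >= threshold$threshold,
                                       "bacterial", "nonbacterial"),
                         stringsAsFactors = FALSE)
  write.table(score_df, file.path(out_dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    threshold = threshold$threshold,
    sensitivity = threshold$sensitivity,
    specificity = threshold$specificity,
    confusion = as.list(threshold$confusion),
    predictive_values = threshold$predictive_values,
    rule = threshold$rule), file.path(out_dir, "threshold_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(packageVersion("bactsig")),
    seed = config$seed,
    config = unclass(config),
    config_hash = digest_config(config),
    filter = list(genes_retained = filtered$report$n_genes_retained,
                  samples_retained = filtered$report$n_samples_retained),
    n_de_significant = sum(de$q < config$fdr),
    lobo_consistency = lobo$consistency_fraction,
    cv_auc = if (!is.null(cv)) cv$cv_auc else NULL,
    signature_genes = model$genes,
    timings_sec = t_all)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(filtered = filtered, de = de, lobo_de = lobo, cv = cv,
                 model = model, threshold = threshold, scores = score_df,
                 external = external, manifest = manifest),
            class = "pipeline_result")
}

# Small deterministic hash of the configuration (sum of serialized bytes).
digest_config <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("bactsig pipeline run\n")
  cat(sprintf("  retained %d genes x %d samples after QC\n",
              x$filtered$report$n_genes_retained,
              x$filtered$report$n_samples_retained))
  cat(sprintf("  DE significant genes (q < %g): %d\n",
              x$manifest$config$fdr, x$manifest$n_de_significant))
  if (!is.na(x$lobo_de$consistency_fraction)) {
    cat(sprintf("  LOBO DE consistency: %.0f%%\n",
                100 * x$lobo_de$consistency_fraction))
  }
  if (!is.null(x$cv)) cat(sprintf("  nested CV-AUC: %.3f\n", x$cv$cv_auc))
  cat(sprintf("  signature: %s\n", paste(x$model$genes, collapse = ", ")))
  cat(sprintf("  threshold %.3f: Se %.1f%%, Sp %.1f%%\n",
              x$threshold$threshold, 100 * x$threshold$sensitivity,
              100 * x$threshold$specificity))
  if (!is.null(x$external)) {
    cat(sprintf("  external validation AUC: %.3f (carried) / %.3f (refit)\n",
                x$external$auc["carried"], x$external$auc["refit"]))
  }
  invisible(x)
}
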