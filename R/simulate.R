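# Cohort simulator: negative-binomial counts with batch structure and a
# planted sparse signature, so every downstream stage can be checked
# against a known ground truth.

#' Configuration for a simulated ARI cohort
#'
#' Builds the parameter list consumed by [simulate_cohort()]. The defaults
#' emulate a hospitalized acute-respiratory-infection study: 7 sequencing
#' batches; 280 viral-alone (V), 129 bacterial-alone (B), 95 mixed
#' viral-bacterial (VB) cases plus 64 non-infected controls (NI); around
#' 8,000 expressed genes surviving a mean-CPM filter; a planted 4-gene
#' signature with three genes elevated under bacterial infection and one
#' interferon-like gene elevated under viral infection; gene-specific
#' negative-binomial dispersion following a log-normal scatter around a
#' mean-dispersion trend; batch-level mean shifts on every gene; and
#' library sizes spanning roughly 8-30 million mapped reads.
#'
#' @param n_genes number of genes to simulate (some fall below the
#'   expression filter by design).
#' @param n_samples_per_class named integer vector with entries `V`, `B`,
#'   `VB`, `NI`.
#' @param n_batches number of sequencing batches; samples of every class
#'   are dealt round-robin across batches.
#' @param signature_spec data frame with columns `gene` (index),
#'   `direction` (`"bacterial"` or `"viral"`) and `effect` (log2 units).
#'   The default plants genes 1-4: three bacterial-up at 1.5 log2-fold and
#'   one viral-up interferon-like gene at 2 log2-fold.
#' @param batch_effect_sd SD (log2 scale) of per-gene batch mean shifts.
#' @param dispersion_model list with `asymptote` (dispersion at high
#'   expression), `extra` (added dispersion scaled by 1/mean-CPM) and
#'   `sdlog` (log-normal scatter of gene dispersions about the trend).
#' @param libsize_range length-2 numeric, min/max expected library size;
#'   library sizes are drawn log-uniformly.
#' @param fraction_null_genes fraction of genes with no class effect at
#'   all; the remainder (minus the signature) become weak DE genes.
#' @param n_weak_de_genes number of weakly differentially expressed
#'   background genes; default derived from `fraction_null_genes`.
#' @param weak_effect list with `meanlog`, `sdlog`: log-normal magnitude of
#'   weak-gene effects (random sign, applied to the bacterial classes).
#' @param vb_viral_attenuation mixing factor: VB samples carry the full
#'   bacterial-direction effects plus this fraction of viral-direction
#'   effects.
#' @param baseline_log2cpm list with `mean`, `sd` of baseline log2-CPM
#'   gene means; signature genes are drawn from a well-expressed stratum
#'   (`sig_mean`, `sig_sd`, floored at `sig_min`) so the planted signal is
#'   not removed by the expression filter.
#' @param seed integer seed governing all randomness of the cohort.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_validation_cohort()]
#' @export
sim_config <- function(n_genes = 8400,
                       n_samples_per_class = c(V = 280, B = 129, VB = 95, NI = 64),
                       n_batches = 7,
                       signature_spec = NULL,
                       batch_effect_sd = 0.3,
                       dispersion_model = list(asymptote = 0.35, extra = 3, sdlog = 0.4),
                       libsize_range = c(8e6, 3e7),
                       fraction_null_genes = 0.6,
                       n_weak_de_genes = NULL,
                       weak_effect = list(meanlog = log(0.35), sdlog = 0.5),
                       vb_viral_attenuation = 0.5,
                       baseline_log2cpm = list(mean = 3.5, sd = 2.2,
                                               sig_mean = 5.5, sig_sd = 1,
                                               sig_min = 3),
                       seed = 1L) {
  if (is.null(signature_spec)) {
    signature_spec <- data.frame(
      gene = 1:4,
      direction = c("bacterial", "bacterial", "bacterial", "viral"),
      effect = c(1.5, 1.5, 1.5, 2.0),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_class = n_samples_per_class,
    n_batches = as.integer(n_batches),
    signature_spec = signature_spec,
    batch_effect_sd = batch_effect_sd,
    dispersion_model = dispersion_model,
    libsize_range = as.numeric(libsize_range),
    fraction_null_genes = fraction_null_genes,
    n_weak_de_genes = n_weak_de_genes,
    weak_effect = weak_effect,
    vb_viral_attenuation = vb_viral_attenuation,
    baseline_log2cpm = baseline_log2cpm,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  n <- cfg$n_samples_per_class
  if (is.null(names(n)) || !all(c("V", "B", "VB", "NI") %in% names(n))) {
    stop("configuration error: n_samples_per_class must name V, B, VB, NI")
  }
  if (any(n < 0) || sum(n[c("V", "B", "VB")]) < 2) {
    stop("configuration error: impossible class sizes")
  }
  if (cfg$n_genes < 1L) stop("configuration error: n_genes must be positive")
  if (cfg$n_batches < 1L) stop("configuration error: n_batches must be positive")
  ss <- cfg$signature_spec
  if (nrow(ss) > 0) {
    if (anyDuplicated(ss$gene)) {
      stop("configuration error: signature gene indices must be distinct")
    }
    if (any(ss$gene < 1L | ss$gene > cfg$n_genes)) {
      stop("configuration error: signature gene index out of range")
    }
    if (!all(ss$direction %in% c("bacterial", "viral"))) {
      stop("configuration error: signature direction must be 'bacterial' or 'viral'")
    }
    if (any(!is.finite(ss$effect))) {
      stop("configuration error: signature effect sizes must be finite")
    }
  }
  dm <- cfg$dispersion_model
  if (dm$asymptote <= 0 || dm$extra < 0 || dm$sdlog < 0) {
    stop("configuration error: non-positive dispersion model")
  }
  if (cfg$libsize_range[1] <= 0 || cfg$libsize_range[1] > cfg$libsize_range[2]) {
    stop("configuration error: libsize_range must satisfy 0 < min <= max")
  }
  if (cfg$batch_effect_sd < 0) stop("configuration error: negative batch_effect_sd")
  if (cfg$fraction_null_genes < 0 || cfg$fraction_null_genes > 1) {
    stop("configuration error: fraction_null_genes outside [0,1]")
  }
  invisible(cfg)
}

# Per-class log2 effect matrix (genes x classes V,B,VB,NI) implied by a
# configuration, including weak background DE genes. Weak genes act in the
# bacterial direction (both B and VB) with random sign.
build_effect_matrix <- function(cfg) {
  E <- matrix(0, cfg$n_genes, 4, dimnames = list(NULL, c("V", "B", "VB", "NI")))
  ss <- cfg$signature_spec
  for (i in seq_len(nrow(ss))) {
    g <- ss$gene[i]
    if (ss$direction[i] == "bacterial") {
      E[g, "B"] <- E[g, "VB"] <- ss$effect[i]
    } else {
      E[g, "V"] <- ss$effect[i]
      E[g, "VB"] <- cfg$vb_viral_attenuation * ss$effect[i]
    }
  }
  n_weak <- cfg$n_weak_de_genes
  if (is.null(n_weak)) {
    n_weak <- max(0L, round((1 - cfg$fraction_null_genes) * cfg$n_genes) - nrow(ss))
  }
  weak_idx <- integer(0)
  if (n_weak > 0) {
    pool <- setdiff(seq_len(cfg$n_genes), ss$gene)
    weak_idx <- sample(pool, min(n_weak, length(pool)))
    eff <- rlnorm(length(weak_idx), cfg$weak_effect$meanlog, cfg$weak_effect$sdlog) *
      sample(c(-1, 1), length(weak_idx), replace = TRUE)
    E[weak_idx, "B"] <- E[weak_idx, "VB"] <- eff
  }
  list(E = E, weak_idx = weak_idx)
}

#' Simulate a multi-batch cohort with a planted sparse signature
#'
#' Draws gene-wise negative-binomial counts whose log2 mean is
#' baseline + class effect + batch shift + log2(library-size factor).
#' VB samples carry the bacterial-direction effects in full plus the
#' viral-direction effect attenuated by `vb_viral_attenuation`. The
#' returned truth object records which genes are differentially expressed,
#' the planted signature, each sample's Bayes-optimal log-likelihood-ratio
#' score over the signature genes (computed with the true generative
#' parameters), and the theoretical AUC of that score estimated by Monte
#' Carlo from fresh draws.
#'
#' @param config a [sim_config()] object.
#' @param n_mc Monte Carlo draws used for the theoretical AUC of the
#'   planted Bayes score.
#' @return List with `counts` (gene x sample numeric matrix of
#'   non-negative integers with dimnames), `annotation` (data frame
#'   `sample_id`, `batch`, `class`) and `truth` (list: `signature`,
#'   `de_status`, `true_log2fc`, `bayes_score`, `theoretical_auc`,
#'   `params`).
#' @export
simulate_cohort <- function(config, n_mc = 4000L) {
  validate_sim_config(config)
  set.seed(config$seed)
  nsc <- config$n_samples_per_class[c("V", "B", "VB", "NI")]
  n <- sum(nsc)
  classes <- rep(names(nsc), nsc)
  sample_id <- sprintf("S%04d", seq_len(n))

  # deal each class round-robin over batches so no batch misses a class
  batch <- integer(n)
  for (cl in names(nsc)) {
    idx <- which(classes == cl)
    if (length(idx)) {
      batch[idx] <- sample(rep_len(seq_len(config$n_batches), length(idx)))
    }
  }

  p <- config$n_genes
  bl <- config$baseline_log2cpm
  baseline <- rnorm(p, bl$mean, bl$sd)
  ss <- config$signature_spec
  if (nrow(ss) > 0) {
    baseline[ss$gene] <- pmax(bl$sig_min, rnorm(nrow(ss), bl$sig_mean, bl$sig_sd))
  }
  dm <- config$dispersion_model
  mean_cpm <- 2^baseline
  trend <- dm$asymptote + dm$extra / mean_cpm
  alpha <- pmin(rlnorm(p, log(trend), dm$sdlog), 5)

  em <- build_effect_matrix(config)
  shift <- matrix(rnorm(p * config$n_batches, 0, config$batch_effect_sd),
                  p, config$n_batches)
  lr <- log(config$libsize_range)
  libsize <- exp(runif(n, lr[1], lr[2]))

  M <- baseline + em$E[, classes, drop = FALSE] + shift[, batch, drop = FALSE]
  mu <- 2^M * rep(libsize / 1e6, each = p)
  counts <- matrix(rnbinom(p * n, size = rep(1 / alpha, n), mu = as.vector(mu)),
                   p, n, dimnames = list(sprintf("G%05d", seq_len(p)), sample_id))

  annotation <- data.frame(sample_id = sample_id, batch = batch,
                           class = classes, stringsAsFactors = FALSE)

  nB <- nsc[["B"]]; nVB <- nsc[["VB"]]
  wB <- if (nB + nVB > 0) nB / (nB + nVB) else 0.5
  true_log2fc <- (wB * em$E[, "B"] + (1 - wB) * em$E[, "VB"]) - em$E[, "V"]
  de_status <- abs(true_log2fc) > 1e-9

  params <- list(baseline = baseline, alpha = alpha, effects = em$E,
                 signature = ss, batch_effect_sd = config$batch_effect_sd,
                 vb_viral_attenuation = config$vb_viral_attenuation,
                 class_prior = c(B = wB, VB = 1 - wB),
                 dispersion_model = dm)

  bayes <- rep(NA_real_, n)
  theo_auc <- NA_real_
  if (nrow(ss) > 0 && nB + nVB > 0 && nsc[["V"]] > 0) {
    sig <- ss$gene
    mu_class <- function(cl, shift_cols, lib) {
      # expected signature-gene counts for hypothetical class cl
      2^(baseline[sig] + em$E[sig, cl] + shift_cols) * lib / 1e6
    }
    llr <- function(x, shift_cols, lib) {
      ll <- sapply(c("V", "B", "VB"), function(cl) {
        sum(dnbinom(x, size = 1 / alpha[sig], mu = mu_class(cl, shift_cols, lib),
                    log = TRUE))
      })
      m <- max(ll["B"] + log(wB + 1e-12), ll["VB"] + log(1 - wB + 1e-12))
      lpos <- m + log(exp(ll["B"] + log(wB + 1e-12) - m) +
                        exp(ll["VB"] + log(1 - wB + 1e-12) - m))
      unname(lpos - ll["V"])
    }
    for (i in seq_len(n)) {
      bayes[i] <- llr(counts[sig, i], shift[sig, batch[i]], libsize[i])
    }
    # Monte Carlo theoretical AUC under fresh draws from the same process
    mc_class <- sample(c("V", "B", "VB"), n_mc, replace = TRUE,
                       prob = c(0.5, 0.5 * wB, 0.5 * (1 - wB)))
    mc_lib <- exp(runif(n_mc, lr[1], lr[2]))
    mc_scores <- numeric(n_mc)
    for (i in seq_len(n_mc)) {
      sh <- rnorm(length(sig), 0, config$batch_effect_sd)
      x <- rnbinom(length(sig), size = 1 / alpha[sig],
                   mu = mu_class(mc_class[i], sh, mc_lib[i]))
      mc_scores[i] <- llr(x, sh, mc_lib[i])
    }
    theo_auc <- auc_rank(mc_scores, as.integer(mc_class != "V"))
  }

  truth <- list(
    signature = ss,
    weak_de_genes = em$weak_idx,
    de_status = de_status,
    true_log2fc = true_log2fc,
    class = setNames(classes, sample_id),
    libsize_factor = setNames(libsize / exp(mean(log(libsize))), sample_id),
    bayes_score = setNames(bayes, sample_id),
    theoretical_auc = theo_auc,
    params = params
  )
  list(counts = counts, annotation = annotation, truth = truth)
}

#' Simulate an independently processed external validation cohort
#'
#' Keeps the planted signature genes and directions from a previously
#' simulated training cohort but redraws everything an independent study
#' would change: batch structure, per-gene baseline means, library-size
#' distribution, and an optional global rescaling of expected counts.
#' Setting `effect_scale = 0` produces a signal-free cohort.
#'
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param n_samples_per_class named vector (`V`, `B`, `VB`, `NI`); the
#'   default emulates an external cohort of 101 bacterial and 123 viral
#'   subjects.
#' @param n_batches batches in the validation cohort.
#' @param libsize_range min/max expected library size (log-uniform draw).
#' @param rescale global multiplier applied to every expected count,
#'   emulating a different quantification pipeline.
#' @param effect_scale multiplier on all class effects (0 removes the
#'   signal, 1 preserves it).
#' @param baseline_shift_sd SD of the per-gene shift added to the training
#'   baselines (independent processing).
#' @param batch_effect_sd SD of the new batch shifts; defaults to the
#'   training value.
#' @param seed integer seed.
#' @return List with `counts` and `annotation` shaped as in
#'   [simulate_cohort()].
#' @export
simulate_validation_cohort <- function(truth,
                                       n_samples_per_class = c(V = 123, B = 101, VB = 0, NI = 0),
                                       n_batches = 3,
                                       libsize_range = c(4e6, 2e7),
                                       rescale = 1,
                                       effect_scale = 1,
                                       baseline_shift_sd = 0.5,
                                       batch_effect_sd = NULL,
                                       seed = 1L) {
  pr <- truth$params
  if (is.null(pr)) stop("truth must come from simulate_cohort()")
  if (rescale <= 0) stop("configuration error: rescale must be positive")
  if (libsize_range[1] <= 0 || libsize_range[1] > libsize_range[2]) {
    stop("configuration error: libsize_range must satisfy 0 < min <= max")
  }
  if (is.null(batch_effect_sd)) batch_effect_sd <- pr$batch_effect_sd
  set.seed(as.integer(seed))
  nsc <- n_samples_per_class[c("V", "B", "VB", "NI")]
  nsc[is.na(nsc)] <- 0
  names(nsc) <- c("V", "B", "VB", "NI")
  n <- sum(nsc)
  if (n < 2) stop("configuration error: impossible class sizes")
  classes <- rep(names(nsc), nsc)
  sample_id <- sprintf("E%04d", seq_len(n))
  batch <- integer(n)
  for (cl in names(nsc)) {
    idx <- which(classes == cl)
    if (length(idx)) batch[idx] <- sample(rep_len(seq_len(n_batches), length(idx)))
  }
  p <- length(pr$baseline)
  baseline <- pr$baseline + rnorm(p, 0, baseline_shift_sd)
  shift <- matrix(rnorm(p * n_batches, 0, batch_effect_sd), p, n_batches)
  lr <- log(libsize_range)
  libsize <- exp(runif(n, lr[1], lr[2]))
  E <- pr$effects * effect_scale
  M <- baseline + E[, classes, drop = FALSE] + shift[, batch, drop = FALSE]
  mu <- 2^M * rep(libsize / 1e6, each = p) * rescale
  counts <- matrix(rnbinom(p * n, size = rep(1 / pr$alpha, n), mu = as.vector(mu)),
                   p, n, dimnames = list(sprintf("G%05d", seq_len(p)), sample_id))
  annotation <- data.frame(sample_id = sample_id, batch = batch,
                           class = classes, stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation)
}
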