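# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default suite stays fast.

# A compact 5-batch cohort with the planted 4-gene signature.
small_cohort <- function(seed = 1, n_genes = 500,
                         n = c(V = 60, B = 28, VB = 20, NI = 8),
                         n_batches = 5, ...) {
  simulate_cohort(sim_config(n_genes = n_genes, n_samples_per_class = n,
                             n_batches = n_batches, seed = seed, ...))
}

# A signal-free cohort: no signature, no weak DE genes.
null_cohort <- function(seed = 1, n_genes = 400,
                        n = c(V = 50, B = 25, VB = 15, NI = 0),
                        n_batches = 4, ...) {
  simulate_cohort(sim_config(
    n_genes = n_genes, n_samples_per_class = n, n_batches = n_batches,
    signature_spec = data.frame(gene = integer(0), direction = character(0),
                                effect = numeric(0)),
    n_weak_de_genes = 0, seed = seed, ...))
}

# Small random standardized design + labels for solver tests.
random_instance <- function(seed, n = 50, p = 10, beta_sd = 0.7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, apply(X, 2, sd), "/")
  y <- rbinom(n, 1, plogis(as.numeric(X %*% rnorm(p, 0, beta_sd))))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}

# Reduced tuning grid used where full-grid resolution is not the point.
fast_grid <- function() {
  tuning_grid(nlambda = 10, gamma = c(0, 0.25, 1), tau = c(0, 0.1))
}

# Brute-force BH step-up straight from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# O(n^2) pairwise AUC with ties counted one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive threshold search over all candidate cut-points.
threshold_bruteforce <- function(scores, labels, target_se) {
  cand <- sort(unique(c(scores, Inf, -Inf)))
  best <- -Inf
  n1 <- sum(labels == 1)
  for (t in cand) {
    se <- sum(scores >= t & labels == 1) / n1
    if (se >= target_se && t > best) best <- t
  }
  best
}
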