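# Synthetic spike-in benchmark: an i.i.d. Gaussian background with additive
# Gaussian noise, plus embedded test genes formed by adding (or subtracting)
# the data maximum u to k cancer samples. Truth labels: a test gene is a
# "positive" (genuine subset outlier) when k is below half the cancer-group
# size, a "biomarker" (negative control, elevated in all cancer samples) when
# k equals it; intermediate k are "ambiguous" and excluded from confusion
# counting.

#' Specification of a synthetic benchmark dataset
#'
#' @param n_genes Number of background genes (default 1000).
#' @param n_samples Total number of samples (default 200).
#' @param mu,sigma Mean and standard deviation of the background expression
#'   distribution (defaults 0 and 1).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 1; set 0 for a noiseless background).
#' @param cancer_size Number of cancer (S1) samples; the benchmark sweep uses
#'   20, 50, 100, 120, 150, 180.
#' @param test_ks Spike sample counts of the embedded test genes; values
#'   exceeding `cancer_size` are dropped for that scenario.
#' @param direction `"amplify"` adds the data maximum `u` to the affected
#'   samples, `"delete"` subtracts it.
#' @param seed Integer seed making the dataset deterministic.
#' @param random_affected If `TRUE`, the `k` affected samples are drawn at
#'   random from S1 instead of taking the first `k` S1 samples.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 1000L, n_samples = 200L, mu = 0,
                            sigma = 1, noise_sd = 1, cancer_size = 50L,
                            test_ks = c(2L, 5L, 10L, 20L, 50L, 80L, 100L,
                                        120L, 150L),
                            direction = c("amplify", "delete"), seed = 1L,
                            random_affected = FALSE) {
  direction <- match.arg(direction)
  stopifnot(n_genes >= 1, n_samples >= 4, sigma > 0, noise_sd >= 0,
            cancer_size >= 2, cancer_size < n_samples, all(test_ks >= 0))
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 mu = mu, sigma = sigma, noise_sd = noise_sd,
                 cancer_size = as.integer(cancer_size),
                 test_ks = as.integer(test_ks),
                 direction = direction, seed = as.integer(seed),
                 random_affected = isTRUE(random_affected)),
            class = "simulation_spec")
}

rand_expr <- function(n, spec) {
  rnorm(n, spec$mu, spec$sigma) + rnorm(n, 0, spec$noise_sd)
}

#' Generate the Gaussian background matrix and its labels
#'
#' Draws `n_genes x n_samples` values from `N(mu, sigma^2)` plus independent
#' `N(0, noise_sd^2)` noise and labels the first `cancer_size` samples as S1.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `matrix` and `labels`.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  m <- spec$n_genes; n <- spec$n_samples
  x <- matrix(rand_expr(m * n, spec), m, n)
  rownames(x) <- sprintf("gene_%04d", seq_len(m))
  colnames(x) <- sprintf("sample_%03d", seq_len(n))
  labels <- sample_labels(colnames(x)[seq_len(spec$cancer_size)],
                          colnames(x)[(spec$cancer_size + 1):n])
  list(matrix = x, labels = labels)
}

#' Embed spike-in test genes into an expression matrix
#'
#' For every `k` in `spec$test_ks` with `k <= cancer_size`, appends one gene
#' row of fresh background draws with the constant `u` (the maximum value of
#' `x` before embedding) added to (`amplify`) or subtracted from (`delete`)
#' `k` cancer samples. Works on the generated background or on any
#' user-supplied matrix. Uses the current RNG state; seed the stream (or use
#' [simulate_dataset()]) for reproducibility.
#'
#' @param x Genes x samples matrix to embed into.
#' @param labels A [sample_labels()] object for `x`.
#' @param spec A [simulation_spec()].
#' @return A list with elements `matrix` (input plus appended `test_k` rows)
#'   and `truth` (data frame `gene_id`, `k`, `label`
#'   (`positive`/`biomarker`/`ambiguous`), `affected_samples` comma-joined).
#' @export
embed_test_genes <- function(x, labels, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  check_labels(x, labels)
  u <- max(x)
  n1 <- length(labels$s1)
  ks <- spec$test_ks[spec$test_ks <= n1]
  shift <- if (spec$direction == "amplify") u else -u
  rows <- matrix(NA_real_, length(ks), ncol(x),
                 dimnames = list(sprintf("test_%d", ks), colnames(x)))
  affected <- character(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    g <- rand_expr(ncol(x), spec)
    names(g) <- colnames(x)
    aff <- if (spec$random_affected) sort(sample(labels$s1, k))
           else labels$s1[seq_len(k)]
    g[aff] <- g[aff] + shift
    rows[j, ] <- g
    affected[j] <- paste(aff, collapse = ",")
  }
  label <- ifelse(ks > 0 & ks < n1 / 2, "positive",
                  ifelse(ks == n1, "biomarker", "ambiguous"))
  truth <- data.frame(gene_id = rownames(rows), k = ks, label = label,
                      affected_samples = affected, stringsAsFactors = FALSE)
  list(matrix = rbind(x, rows), truth = truth, u = u)
}

#' Generate one complete benchmark dataset
#'
#' [generate_background()] followed by [embed_test_genes()] under a single
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `simulated_dataset` with elements `matrix`,
#'   `labels`, `truth`, `u` and `spec`.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_spec(n_genes = 50, n_samples = 20,
#'                                        cancer_size = 6, test_ks = c(2, 6),
#'                                        seed = 1))
#' ds$truth
simulate_dataset <- function(spec) {
  bg <- generate_background(spec)
  emb <- embed_test_genes(bg$matrix, bg$labels, spec)
  structure(list(matrix = emb$matrix, labels = bg$labels, truth = emb$truth,
                 u = emb$u, spec = spec),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples; |S1| =", length(x$labels$s1), "; test genes:",
      paste(x$truth$gene_id, collapse = " "), "\n")
  invisible(x)
}

#' Benchmark sweep over cancer-group sizes
#'
#' One [simulate_dataset()] per cancer-group size, with per-scenario seeds
#' derived deterministically from the base seed (`seed + index - 1`).
#'
#' @param spec Base [simulation_spec()].
#' @param cancer_sizes Integer vector of cancer-group sizes
#'   (default `c(20, 50, 100, 120, 150, 180)`).
#' @return A list of `simulated_dataset` objects.
#' @export
scenario_sweep <- function(spec,
                           cancer_sizes = c(20L, 50L, 100L, 120L, 150L, 180L)) {
  stopifnot(inherits(spec, "simulation_spec"))
  lapply(seq_along(cancer_sizes), function(i) {
    sp <- spec
    sp$cancer_size <- as.integer(cancer_sizes[i])
    sp$seed <- spec$seed + i - 1L
    simulate_dataset(sp)
  })
}
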