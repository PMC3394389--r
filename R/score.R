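# Core scoring. Each retained gene i contributes
#   Score_i = E(xhat_i) * (E1_i - E2_i) / E(xhat[-i, ])
# where E() is the rank-one energy (sum of squares), E1/E2 are the energies of
# the transformed profile over the cancer and normal groups, and the
# denominator is the leave-one-out top eigenvalue of the transformed matrix.
# By default E1 and E2 are per-sample mean energies so that the group contrast
# is comparable across cancer-group sizes; `group_energy = "sum"` gives the
# raw summed energies instead (identical ranking when |S1| == |S2|).

ef_quantile <- function(v, p) unname(quantile(v, p, type = 7, names = FALSE))

# Tukey-fence outlier calls on the transformed profile of one gene: samples
# whose transformed value lies outside [q25 - f*IQR, q75 + f*IQR] of the
# gene's whole transformed profile; restricted to cancer samples.
fence_outliers <- function(xhat_row, s1_ids, fence_multiplier) {
  q <- ef_quantile(xhat_row, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lo <- q[1] - fence_multiplier * iqr
  hi <- q[2] + fence_multiplier * iqr
  v1 <- xhat_row[s1_ids]
  out <- v1 < lo | v1 > hi
  list(samples = s1_ids[out], values = v1[out])
}

call_direction <- function(outlier_values) {
  if (length(outlier_values) == 0) return("mixed")
  if (all(outlier_values > 0)) return("over")
  if (all(outlier_values < 0)) return("under")
  "mixed"
}

# stable descending ranks: ties broken by input order
stable_rank <- function(score) {
  ord <- order(-score)   # order() is stable, preserving input order on ties
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

# scores for retained genes given precomputed row stats; used by both the
# observed scoring and the permutation null
ef_raw_scores <- function(x, s1_idx, s2_idx, overall_median, madv, keep,
                          group_energy) {
  xk <- x[keep, , drop = FALSE]
  avg <- vapply(seq_len(nrow(xk)), function(i) {
    v <- xk[i, s1_idx]
    m1 <- median(v)
    upper <- v[v > m1]
    lower <- v[v < m1]
    (m1 + (if (length(upper)) median(upper) else m1) +
       (if (length(lower)) median(lower) else m1)) / 3
  }, numeric(1))
  xhat <- (xk - avg) / madv[keep]
  E <- rowSums(xhat^2)
  e1 <- rowSums(xhat[, s1_idx, drop = FALSE]^2)
  e2 <- rowSums(xhat[, s2_idx, drop = FALSE]^2)
  if (group_energy == "mean") {
    e1 <- e1 / length(s1_idx)
    e2 <- e2 / length(s2_idx)
  }
  denom <- loo_energies(xhat)
  list(score = E * (e1 - e2) / denom, xhat = xhat)
}

#' Score genes for subset over-/under-expression
#'
#' Ranks genes by the eigenvalue-based outlier statistic: the rank-one energy
#' of the transformed profile times the difference between its cancer-group
#' and normal-group energies, normalized by the leave-one-out top eigenvalue
#' of the transformed matrix. Genes over- or under-expressed in a *subset* of
#' cancer samples receive large positive scores; genes shifted in (nearly)
#' all cancer samples are centered away by the transformation and rank at the
#' bottom.
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param labels A [sample_labels()] object.
#' @param config A [run_config()]; `fence_multiplier` controls the
#'   outlier-sample fence, `top_n` is not used here.
#' @param group_energy `"mean"` (default) compares per-sample mean energies of
#'   the two groups, making the contrast comparable across cancer-group
#'   sizes; `"sum"` uses the raw summed energies.
#' @return A data frame of class `gene_score_table` with columns `gene`,
#'   `score`, `rank` (1 = best, stable ties), `p_value` (`NA` until
#'   [permutation_pvalues()]), `direction` (`over`/`under`/`mixed`),
#'   `n_outlier_samples`, `outlier_samples` (comma-joined cancer sample IDs
#'   beyond the Tukey fence). Genes dropped for zero MAD are absent; they are
#'   listed in `attr(., "dropped_genes")`.
#' @export
eigfusion_scores <- function(x, labels, config = run_config(),
                             group_energy = c("mean", "sum")) {
  group_energy <- match.arg(group_energy)
  stopifnot(inherits(config, "run_config"))
  tr <- ef_transform(x, labels)
  if (length(tr$gene_ids) < 2)
    stop("need at least 2 retained genes to score")
  s1_idx <- match(labels$s1, colnames(x))
  s2_idx <- match(labels$s2, colnames(x))
  st <- robust_row_stats(x, s1_idx)
  keep <- st$mad > 0
  rs <- ef_raw_scores(x, s1_idx, s2_idx, st$overall_median, st$mad, keep,
                      group_energy)
  xhat <- rs$xhat
  outs <- lapply(seq_len(nrow(xhat)), function(i)
    fence_outliers(xhat[i, ], labels$s1, config$fence_multiplier))
  tab <- data.frame(
    gene = tr$gene_ids,
    score = rs$score,
    rank = stable_rank(rs$score),
    p_value = NA_real_,
    direction = vapply(outs, function(o) call_direction(o$values), character(1)),
    n_outlier_samples = vapply(outs, function(o) length(o$samples), integer(1)),
    outlier_samples = vapply(outs, function(o) paste(o$samples, collapse = ","),
                             character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  attr(tab, "dropped_genes") <- tr$dropped_genes
  attr(tab, "method") <- "eigfusion"
  class(tab) <- c("gene_score_table", "data.frame")
  tab
}

#' Permutation p-values for the outlier score
#'
#' Repeatedly permutes the sample labels (preserving the cancer-group size),
#' recomputes all scores, and pools the permuted scores of all genes into one
#' null distribution. With `P` permutations of `G` genes the attainable
#' minimum is `1/(1 + G*P)`, so the default 100 permutations can resolve
#' p-values well below a per-gene permutation scheme. The p-value of gene `g`
#' is `(1 + #/{null >= score_g}) / (1 + G*P)`.
#'
#' @inheritParams eigfusion_scores
#' @param config A [run_config()]; uses `n_permutations`, `p_threshold`,
#'   `fence_multiplier` and `seed`.
#' @return The [eigfusion_scores()] table with `p_value` filled and a logical
#'   `significant` column (`p_value < p_threshold`).
#' @export
permutation_pvalues <- function(x, labels, config = run_config(),
                                group_energy = c("mean", "sum")) {
  group_energy <- match.arg(group_energy)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tab <- eigfusion_scores(x, labels, config, group_energy)
  s1_idx <- match(labels$s1, colnames(x))
  s2_idx <- match(labels$s2, colnames(x))
  st <- robust_row_stats(x, s1_idx)
  keep <- st$mad > 0
  n1 <- length(s1_idx)
  all_idx <- seq_len(ncol(x))
  nperm <- config$n_permutations
  null_scores <- vector("list", nperm)
  for (b in seq_len(nperm)) {
    p1 <- sample(all_idx, n1)
    p2 <- setdiff(all_idx, p1)
    null_scores[[b]] <- ef_raw_scores(x, p1, p2, st$overall_median, st$mad,
                                      keep, group_energy)$score
  }
  pool <- sort(unlist(null_scores))
  n_null <- length(pool)
  # #{null >= s} via binary search on the sorted pool
  geq <- n_null - findInterval(tab$score, pool, left.open = TRUE)
  tab$p_value <- (1 + geq) / (1 + n_null)
  tab$significant <- tab$p_value < config$p_threshold
  tab
}
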