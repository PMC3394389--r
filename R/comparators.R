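# Comparator outlier statistics. All of them standardize each gene robustly
# (overall median / raw MAD, or the normal-group analogue for ORT) so every
# statistic is invariant under location and positive-scale changes of a
# gene's raw values. Quantiles use linear interpolation between order
# statistics (stats::quantile type 7) and ranks are stable descending.

comparator_table <- function(gene, score, method, dropped = NULL) {
  tab <- data.frame(gene = gene, score = score, rank = stable_rank(score),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  attr(tab, "method") <- method
  attr(tab, "dropped_genes") <- dropped
  class(tab) <- c("comparator_result", "data.frame")
  tab
}

# overall-median / raw-MAD standardization of each row; rows with zero MAD
# are flagged
median_mad_standardize <- function(x) {
  om <- apply(x, 1L, median)
  madv <- apply(abs(x - om), 1L, median)
  list(xt = (x - om) / ifelse(madv > 0, madv, NA_real_), mad = madv)
}

#' COPA: percentile of robustly standardized cancer values
#'
#' Standardizes each gene by its overall median and raw median absolute
#' deviation and takes a fixed percentile (default the 80th) of the
#' standardized cancer-group values. Genes with zero MAD are dropped.
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param labels A [sample_labels()] object.
#' @param percentile Percentile in (0, 100) of the standardized cancer values.
#' @return A `comparator_result` data frame with columns `gene`, `score`,
#'   `rank`.
#' @export
copa_scores <- function(x, labels, percentile = 80) {
  check_labels(x, labels)
  stopifnot(percentile > 0, percentile < 100)
  std <- median_mad_standardize(x)
  keep <- std$mad > 0
  xt <- std$xt[keep, , drop = FALSE]
  s1 <- match(labels$s1, colnames(x))
  stat <- apply(xt[, s1, drop = FALSE], 1L, ef_quantile, p = percentile / 100)
  dropped <- data.frame(gene_id = rownames(x)[!keep],
                        reason = rep("zero MAD", sum(!keep)),
                        stringsAsFactors = FALSE)
  comparator_table(rownames(x)[keep], stat, "copa", dropped)
}

#' OS: outlier sum over the standardized profile fence
#'
#' Standardizes each gene by its overall median and raw MAD and sums the
#' standardized cancer values strictly exceeding the upper Tukey fence
#' `q75 + fence*IQR` of the standardized whole profile. Genes with no
#' exceedances (or zero MAD) score 0.
#'
#' @inheritParams copa_scores
#' @param fence Fence multiplier on the IQR (1 in the original definition).
#' @export
os_scores <- function(x, labels, fence = 1) {
  check_labels(x, labels)
  std <- median_mad_standardize(x)
  s1 <- match(labels$s1, colnames(x))
  stat <- vapply(seq_len(nrow(x)), function(i) {
    if (!(std$mad[i] > 0)) return(0)
    xt <- std$xt[i, ]
    q <- ef_quantile(xt, c(0.25, 0.75))
    thr <- q[2] + fence * (q[2] - q[1])
    v <- xt[s1]
    sum(v[v > thr])
  }, numeric(1))
  comparator_table(rownames(x), stat, "os")
}

#' ORT: outlier sum against the normal-group fence
#'
#' Centers each gene at the normal-group median, scales by the median
#' absolute deviation about the two group medians, and sums the scaled
#' cancer values strictly exceeding `q75 + IQR` of the scaled normal values.
#' Genes with no exceedances (or zero scale) score 0.
#'
#' @inheritParams os_scores
#' @export
ort_scores <- function(x, labels, fence = 1) {
  check_labels(x, labels)
  s1 <- match(labels$s1, colnames(x))
  s2 <- match(labels$s2, colnames(x))
  stat <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    m1 <- median(v[s1])
    m2 <- median(v[s2])
    sc <- median(c(abs(v[s1] - m1), abs(v[s2] - m2)))
    if (!(sc > 0)) return(0)
    u <- (v - m2) / sc
    q <- ef_quantile(u[s2], c(0.25, 0.75))
    thr <- q[2] + fence * (q[2] - q[1])
    w <- u[s1]
    sum(w[w > thr])
  }, numeric(1))
  comparator_table(rownames(x), stat, "ort")
}

#' GTI: outlier proportion weighted by robust exceedance
#'
#' On the overall-median / raw-MAD standardized profile, cancer-group
#' outliers are values above `q75(S1) + fence*IQR(S1)`; the statistic is the
#' outlier proportion times the mean exceedance of the outliers over
#' `q75(S1)`, divided by the robust scale `max(|median|, MAD)` of the
#' standardized profile. Genes with no outliers (or zero MAD) score 0.
#'
#' @inheritParams os_scores
#' @export
gti_scores <- function(x, labels, fence = 1) {
  check_labels(x, labels)
  std <- median_mad_standardize(x)
  s1 <- match(labels$s1, colnames(x))
  n1 <- length(s1)
  stat <- vapply(seq_len(nrow(x)), function(i) {
    if (!(std$mad[i] > 0)) return(0)
    xt <- std$xt[i, ]
    v <- xt[s1]
    q <- ef_quantile(v, c(0.25, 0.75))
    thr <- q[2] + fence * (q[2] - q[1])
    out <- v[v > thr]
    if (length(out) == 0) return(0)
    scale <- max(abs(median(xt)), median(abs(xt - median(xt))))
    if (!(scale > 0)) return(0)
    (length(out) / n1) * (mean(out) - q[2]) / scale
  }, numeric(1))
  comparator_table(rownames(x), stat, "gti")
}

#' Two-sample Kolmogorov-Smirnov statistic per gene
#'
#' The maximum absolute difference between the empirical distribution
#' functions of the cancer and normal values of each gene.
#'
#' @inheritParams copa_scores
#' @export
ks_scores <- function(x, labels) {
  check_labels(x, labels)
  s1 <- match(labels$s1, colnames(x))
  s2 <- match(labels$s2, colnames(x))
  stat <- vapply(seq_len(nrow(x)), function(i) {
    unname(suppressWarnings(
      ks.test(x[i, s1], x[i, s2], exact = FALSE)$statistic))
  }, numeric(1))
  comparator_table(rownames(x), stat, "ks")
}

#' Score genes with any of the implemented methods
#'
#' Dispatcher used by the command-line interface and the benchmark: runs the
#' requested statistic and returns its ranking table.
#'
#' @inheritParams eigfusion_scores
#' @param method One of `"eigfusion"`, `"copa"`, `"os"`, `"ort"`, `"gti"`,
#'   `"ks"`.
#' @return A `gene_score_table` (for eigfusion) or `comparator_result`.
#' @export
outlier_scores <- function(x, labels,
                           method = c("eigfusion", "copa", "os", "ort",
                                      "gti", "ks"),
                           config = run_config()) {
  method <- match.arg(method)
  switch(method,
         eigfusion = eigfusion_scores(x, labels, config),
         copa = copa_scores(x, labels, config$copa_percentile),
         os = os_scores(x, labels, config$fence_multiplier),
         ort = ort_scores(x, labels, config$fence_multiplier),
         gti = gti_scores(x, labels, config$fence_multiplier),
         ks = ks_scores(x, labels))
}
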