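# Robust standardization of a gene profile around the cancer-group median
# structure. Centering uses the average of three cancer-group medians so that
# genes shifted in (nearly) all cancer samples are centered at their shifted
# level and lose their apparent outlier signal; the scale is the raw median
# absolute deviation of the whole profile (no 1.4826 consistency factor).

#' Three-median summary of a gene over the cancer group
#'
#' Computes the cancer-group median, the medians of the cancer values strictly
#' above and strictly below it (an empty strict subgroup contributes the
#' group median itself), their average (the centering constant of the
#' transformation), the whole-profile median, and the raw median absolute
#' deviation about the whole-profile median (the transformation scale).
#' Even-length medians use the midpoint convention.
#'
#' @param gene_values Numeric vector of one gene's expression over all
#'   samples, named by sample ID (names are required to resolve the groups).
#' @param labels A [sample_labels()] object.
#' @return A list of class `median_summary` with elements `median_s1`,
#'   `median_upper`, `median_lower`, `avg_median_s1`, `overall_median`, `mad`.
#' @export
#' @examples
#' v <- setNames(1:8, paste0("s", 1:8))
#' lab <- sample_labels(paste0("s", 5:8), paste0("s", 1:4))
#' median_summary(v, lab)
median_summary <- function(gene_values, labels) {
  stopifnot(inherits(labels, "sample_labels"), !is.null(names(gene_values)))
  s1 <- gene_values[labels$s1]
  if (anyNA(s1)) stop("cancer samples missing from gene_values")
  m1 <- median(s1)
  upper <- s1[s1 > m1]
  lower <- s1[s1 < m1]
  mu <- if (length(upper)) median(upper) else m1
  ml <- if (length(lower)) median(lower) else m1
  om <- median(gene_values)
  structure(list(median_s1 = m1, median_upper = mu, median_lower = ml,
                 avg_median_s1 = (m1 + mu + ml) / 3,
                 overall_median = om,
                 mad = median(abs(gene_values - om))),
            class = "median_summary")
}

# vectorized centering constants and scales for all rows of x
robust_row_stats <- function(x, s1_idx) {
  m1v <- apply(x[, s1_idx, drop = FALSE], 1L, median)
  avg <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, s1_idx]
    m1 <- m1v[i]
    upper <- v[v > m1]
    lower <- v[v < m1]
    (m1 + (if (length(upper)) median(upper) else m1) +
       (if (length(lower)) median(lower) else m1)) / 3
  }, numeric(1))
  om <- apply(x, 1L, median)
  madv <- apply(abs(x - om), 1L, median)
  list(avg_median_s1 = avg, overall_median = om, mad = madv)
}

#' Transform an expression matrix for outlier-gene scoring
#'
#' Standardizes every gene as `(x - avg_median_s1) / mad` where
#' `avg_median_s1` is the three-median average over the cancer group (see
#' [median_summary()]) and `mad` is the raw median absolute deviation of the
#' whole profile. Genes with zero MAD are undefined under this map and are
#' dropped (reported in `dropped_genes`), not zero-filled, so they cannot
#' distort the leave-one-out spectral denominator.
#'
#' The transformation is invariant under positive affine changes of a gene's
#' raw values: `transform(a*x + b) == transform(x)` for `a > 0`.
#'
#' @param x Numeric genes x samples matrix with gene and sample IDs as
#'   dimnames.
#' @param labels A [sample_labels()] object partitioning `colnames(x)`.
#' @return A list of class `ef_transform` with elements `values` (the
#'   transformed matrix over retained genes), `gene_ids`, `sample_ids`,
#'   `labels`, and `dropped_genes` (data frame of `gene_id`, `reason`).
#' @export
ef_transform <- function(x, labels) {
  check_labels(x, labels)
  if (is.null(rownames(x))) stop("matrix must have gene IDs as row names")
  s1_idx <- match(labels$s1, colnames(x))
  st <- robust_row_stats(x, s1_idx)
  keep <- st$mad > 0
  if (!any(keep)) stop("no scorable genes: every gene has zero MAD")
  xhat <- (x[keep, , drop = FALSE] - st$avg_median_s1[keep]) / st$mad[keep]
  dropped <- data.frame(gene_id = rownames(x)[!keep],
                        reason = rep("zero MAD", sum(!keep)),
                        stringsAsFactors = FALSE)
  structure(list(values = xhat,
                 gene_ids = rownames(x)[keep],
                 sample_ids = colnames(x),
                 labels = labels,
                 dropped_genes = dropped),
            class = "ef_transform")
}

#' @export
print.ef_transform <- function(x, ...) {
  cat("ef_transform:", length(x$gene_ids), "retained genes x",
      length(x$sample_ids), "samples;", nrow(x$dropped_genes),
      "dropped (zero MAD)\n")
  invisible(x)
}
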