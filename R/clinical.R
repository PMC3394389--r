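# Clinical association. A gene's putative rearrangement is summarized as a
# binary vector over the cancer samples (1 = the sample's transformed value
# lies beyond the Tukey fence of the gene's transformed profile); association
# with a binary clinical vector (death, aggressiveness) is measured by the
# normalized Hamming distance, together with the conditional rate
# P(clinical = 1 | rearranged = 1), since a small distance is usually read as
# "most rearranged samples have the outcome" and the two only coincide when
# the vectors' supports align.

#' Binary rearrangement vector of a gene over the cancer samples
#'
#' Bit 1 marks cancer samples whose transformed value lies outside the Tukey
#' fence `[q25 - f*IQR, q75 + f*IQR]` of the gene's whole transformed
#' profile (the same rule as the `outlier_samples` column of
#' [eigfusion_scores()]). Vectors are defined over S1 only, since clinical
#' outcomes attach to tumor samples.
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param labels A [sample_labels()] object.
#' @param gene_id Gene to summarize; must be retained by the transformation.
#' @param config A [run_config()]; uses `fence_multiplier`.
#' @return An integer 0/1 vector of class `binary_vector` named by the S1
#'   sample IDs.
#' @export
rearrangement_vector <- function(x, labels, gene_id, config = run_config()) {
  tr <- ef_transform(x, labels)
  if (!gene_id %in% rownames(x)) stop("unknown gene: ", gene_id)
  if (!gene_id %in% tr$gene_ids)
    stop("gene '", gene_id, "' was dropped (zero MAD); no rearrangement vector")
  row <- tr$values[match(gene_id, tr$gene_ids), ]
  out <- fence_outliers(row, labels$s1, config$fence_multiplier)
  bits <- setNames(integer(length(labels$s1)), labels$s1)
  bits[out$samples] <- 1L
  structure(bits, class = "binary_vector")
}

#' Hamming-distance association between two binary vectors
#'
#' Aligns the vectors by sample ID (the sample sets must coincide) and
#' returns the normalized Hamming distance (# mismatches / length) together
#' with the conditional rate `P(clinical = 1 | v = 1)` and the number of
#' rearranged samples.
#'
#' @param v Binary rearrangement vector (named 0/1, e.g. from
#'   [rearrangement_vector()]).
#' @param clinical Binary clinical vector (named 0/1; 1 = death or
#'   aggressive).
#' @return A list with `distance`, `conditional_rate` (`NA` when `v` has no
#'   1s) and `n_rearranged`.
#' @export
#' @examples
#' v <- c(s1 = 1, s2 = 1, s3 = 0, s4 = 0)
#' cl <- c(s1 = 1, s2 = 0, s3 = 0, s4 = 0)
#' hamming_association(v, cl) # distance 0.25, conditional rate 0.5
hamming_association <- function(v, clinical) {
  if (is.null(names(v)) || is.null(names(clinical)))
    stop("both vectors must be named by sample ID")
  if (!setequal(names(v), names(clinical)))
    stop("sample sets differ between the two vectors")
  cl <- clinical[names(v)]
  if (!all(unclass(v) %in% c(0, 1)) || !all(cl %in% c(0, 1)))
    stop("vectors must be binary 0/1")
  mism <- sum(v != cl)
  n1 <- sum(v == 1)
  list(distance = mism / length(v),
       conditional_rate = if (n1 > 0) sum(cl[v == 1] == 1) / n1 else NA_real_,
       n_rearranged = n1)
}

#' Read a two-column binary clinical vector file
#'
#' @param path Two-column text file (sample_id, 0/1), no header.
#' @return A named integer 0/1 vector.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE)
  bits <- as.integer(tab[[2]])
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("clinical values must be 0 or 1")
  setNames(bits, as.character(tab[[1]]))
}
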