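# Evaluation of a ranking against the embedded truth set. Confusion counts
# are taken over labeled test genes only: a false positive is a biomarker
# test gene (spiked in all cancer samples) entering the top list, a false
# negative is a positive test gene (spiked in less than half of them) missing
# from it. Background genes inside the top list are reported separately as
# "background intrusions" and do not enter the rates. The reported FPR/FNR
# are false *discovery* proportions, FP/(FP+TP) and FN/(FN+TN), not ROC
# rates; both are defined as 0 when their denominator is 0.

#' Top-list confusion counts over labeled test genes
#'
#' @param ranking A `gene_score_table` or `comparator_result` (any data frame
#'   with `gene` and `rank` columns).
#' @param truth Truth data frame from [simulate_dataset()] (columns
#'   `gene_id`, `label`).
#' @param top_n Size of the top list (default 10).
#' @return A list of class `confusion_counts` with integer elements `tp`,
#'   `fp`, `tn`, `fn` and `background_intrusions`. Truth genes absent from
#'   the ranking (e.g. dropped for zero MAD) are counted as `fn` if positive
#'   and `tn` if biomarker, with a warning.
#' @export
confusion_counts <- function(ranking, truth, top_n = 10L) {
  stopifnot(is.data.frame(ranking), all(c("gene", "rank") %in% names(ranking)),
            is.data.frame(truth))
  pos <- truth$gene_id[truth$label == "positive"]
  bio <- truth$gene_id[truth$label == "biomarker"]
  rk <- setNames(ranking$rank, ranking$gene)
  missing <- setdiff(c(pos, bio), names(rk))
  if (length(missing))
    warning("truth genes absent from ranking (counted as misses): ",
            paste(missing, collapse = ", "))
  in_top <- function(g) g %in% names(rk) & rk[g] <= top_n
  tp <- sum(in_top(pos))
  fn <- length(pos) - tp
  fp <- sum(in_top(bio))
  tn <- length(bio) - fp
  top_genes <- ranking$gene[ranking$rank <= top_n]
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 background_intrusions =
                   sum(!top_genes %in% truth$gene_id)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: tp=%d fp=%d tn=%d fn=%d (background intrusions: %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$background_intrusions))
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f = 2*precision*recall/(precision+recall)`; 0 when precision and recall
#' are both undefined or zero.
#'
#' @param counts A [confusion_counts()] object (or list with `tp`, `fp`,
#'   `fn`).
#' @return A scalar in \[0, 1\].
#' @export
#' @examples
#' f_measure(list(tp = 3, fp = 1, fn = 1)) # 0.75
f_measure <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve for recovering positive test genes
#'
#' Positives are the `positive` test genes; negatives are all background
#' genes plus the `biomarker` test genes (ambiguous test genes are excluded).
#' The AUC is the probability that a positive outscores a negative, ties
#' counted one half, computed from rank sums; it equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores Named numeric vector of per-gene statistics, or a data frame
#'   with `gene` and `score` columns.
#' @param truth Truth data frame (columns `gene_id`, `label`).
#' @return A scalar in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$gene)
  pos <- intersect(truth$gene_id[truth$label == "positive"], names(scores))
  excl <- truth$gene_id[truth$label == "ambiguous"]
  neg <- setdiff(names(scores), c(truth$gene_id[truth$label == "positive"], excl))
  if (length(pos) == 0) stop("no positive test genes in scores")
  if (length(neg) == 0) stop("no negative genes in scores")
  s <- scores[c(pos, neg)]
  r <- rank(s)
  npos <- length(pos); nneg <- length(neg)
  (sum(r[seq_len(npos)]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Run all methods over a benchmark sweep
#'
#' Scores every dataset with every requested method and evaluates each
#' ranking against the dataset's truth set.
#'
#' @param datasets A list of `simulated_dataset` objects
#'   (see [scenario_sweep()]).
#' @param methods Character vector of method names accepted by
#'   [outlier_scores()].
#' @param config A [run_config()]; `top_n` sets the confusion top list.
#' @return A data frame with one row per (method, cancer_size):
#'   `method`, `cancer_size`, `tp`, `fp`, `tn`, `fn`, `fpr`, `fnr`,
#'   `f_measure`, `auc`, `background_intrusions`.
#' @export
run_benchmark <- function(datasets,
                          methods = c("eigfusion", "copa", "os", "ort",
                                      "gti", "ks"),
                          config = run_config()) {
  stopifnot(length(datasets) > 0)
  rows <- lapply(datasets, function(ds) {
    stopifnot(inherits(ds, "simulated_dataset"))
    do.call(rbind, lapply(methods, function(me) {
      tab <- outlier_scores(ds$matrix, ds$labels, me, config)
      cc <- confusion_counts(tab, ds$truth, config$top_n)
      fpr <- if (cc$fp + cc$tp > 0) cc$fp / (cc$fp + cc$tp) else 0
      fnr <- if (cc$fn + cc$tn > 0) cc$fn / (cc$fn + cc$tn) else 0
      auc <- tryCatch(roc_auc(tab, ds$truth), error = function(e) NA_real_)
      data.frame(method = me, cancer_size = length(ds$labels$s1),
                 tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                 fpr = fpr, fnr = fnr, f_measure = f_measure(cc), auc = auc,
                 background_intrusions = cc$background_intrusions,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
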