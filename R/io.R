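#' Run configuration
#'
#' Bundles the tunable parameters shared by the scoring, permutation and
#' evaluation functions. All values can be serialized to a flat `key=value`
#' text file with [write_config()] and restored with [read_config()].
#'
#' @param n_permutations Number of label permutations for [permutation_pvalues()].
#' @param p_threshold Significance threshold applied to permutation p-values.
#' @param top_n Size of the top list used for confusion counting.
#' @param copa_percentile Percentile (in (0,100)) used by [copa_scores()].
#' @param fence_multiplier Multiplier `f` of the Tukey fence `q75 + f*IQR`
#'   used for outlier-sample calls and the GTI outlier set.
#' @param seed Integer seed for every stochastic step; `NULL` leaves the RNG
#'   state untouched.
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(n_permutations = 50, seed = 1)
#' cfg$top_n
run_config <- function(n_permutations = 100L, p_threshold = 0.001, top_n = 10L,
                       copa_percentile = 80, fence_multiplier = 1.0,
                       seed = NULL) {
  stopifnot(n_permutations >= 1, p_threshold > 0, p_threshold < 1, top_n >= 1,
            copa_percentile > 0, copa_percentile < 100, fence_multiplier >= 0)
  structure(list(n_permutations = as.integer(n_permutations),
                 p_threshold = as.numeric(p_threshold),
                 top_n = as.integer(top_n),
                 copa_percentile = as.numeric(copa_percentile),
                 fence_multiplier = as.numeric(fence_multiplier),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the flat `key=value` config file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- config[!vapply(config, is.null, logical(1))]
  lines <- sprintf("%s=%s", names(vals),
                   vapply(vals, function(v) format(v, digits = 15), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(lapply(kv, function(p) as.numeric(p[2])),
                   vapply(kv, `[`, character(1), 1))
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Read a genes x samples expression matrix
#'
#' Expects a delimited text file whose first row holds sample identifiers and
#' whose first column holds gene identifiers. Values are used as supplied
#' (no log transform or normalization is applied).
#'
#' @param path Path to a tab- or comma-separated file.
#' @param delimiter Field delimiter; auto-detected from the first line
#'   (tab vs comma) when `NULL`.
#' @return A numeric matrix with gene IDs as row names and sample IDs as
#'   column names. Duplicate identifiers, non-numeric or non-finite cells are
#'   load errors that name the offending gene/sample.
#' @export
read_expression <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  raw <- read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"", comment.char = "",
                    na.strings = character(0), stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file must have at least one sample column")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = length(gene_ids),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite expression value for gene '",
         gene_ids[bad[1, 1]], "', sample '", sample_ids[bad[1, 2]], "'")
  }
  vals
}

#' @rdname read_expression
#' @param x Numeric genes x samples matrix with dimnames.
#' @export
write_expression <- function(x, path, delimiter = "\t") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_labels
#' @param labels A [sample_labels()] object to serialize.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "sample_labels"))
  df <- data.frame(sample_id = c(labels$s1, labels$s2),
                   group = rep(c("S1", "S2"),
                               c(length(labels$s1), length(labels$s2))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Sample labels: cancer (S1) versus normal (S2)
#'
#' @param s1 Character vector of cancer sample IDs.
#' @param s2 Character vector of normal sample IDs.
#' @return A list of class `sample_labels` with elements `s1` and `s2`.
#' @export
#' @examples
#' sample_labels(c("t1", "t2"), c("n1", "n2"))
sample_labels <- function(s1, s2) {
  s1 <- as.character(s1); s2 <- as.character(s2)
  if (anyDuplicated(c(s1, s2)))
    stop("sample IDs duplicated within or across groups: ",
         paste(unique(c(s1, s2)[duplicated(c(s1, s2))]), collapse = ", "))
  if (length(s1) < 2 || length(s2) < 2)
    stop("each group needs at least 2 samples (|S1|=", length(s1),
         ", |S2|=", length(s2), ")")
  structure(list(s1 = s1, s2 = s2), class = "sample_labels")
}

#' @export
print.sample_labels <- function(x, ...) {
  cat("sample_labels: |S1| =", length(x$s1), "(cancer), |S2| =",
      length(x$s2), "(normal)\n")
  invisible(x)
}

# labels must exactly cover the matrix columns
check_labels <- function(x, labels) {
  stopifnot(is.matrix(x), inherits(labels, "sample_labels"))
  ids <- c(labels$s1, labels$s2)
  missing_m <- setdiff(ids, colnames(x))
  if (length(missing_m))
    stop("labeled samples absent from matrix: ", paste(missing_m, collapse = ", "))
  missing_l <- setdiff(colnames(x), ids)
  if (length(missing_l))
    stop("matrix samples missing from labels: ", paste(missing_l, collapse = ", "))
  invisible(TRUE)
}

#' Read a two-column sample label file
#'
#' Each line holds a sample ID and a group token (no header). Group tokens are
#' matched case-insensitively against the alias sets; unknown tokens are an
#' error.
#'
#' @param path Path to a two-column delimited text file.
#' @param x Expression matrix the labels must cover exactly.
#' @param aliases Named list with elements `s1` and `s2` of accepted group
#'   tokens.
#' @return A [sample_labels()] object whose groups partition `colnames(x)`.
#' @export
read_labels <- function(path, x,
                        aliases = list(s1 = c("S1", "cancer", "tumor"),
                                       s2 = c("S2", "normal", "benign"))) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- read.table(path, sep = "", header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("label file must have two columns: sample_id, group")
  ids <- tab[[1]]; grp <- tolower(tab[[2]])
  in1 <- grp %in% tolower(aliases$s1)
  in2 <- grp %in% tolower(aliases$s2)
  if (any(!in1 & !in2))
    stop("unknown group token(s): ",
         paste(unique(tab[[2]][!in1 & !in2]), collapse = ", "))
  labels <- sample_labels(ids[in1], ids[in2])
  check_labels(x, labels)
  labels
}

#' Write/read a per-gene score table
#'
#' Writes a tab-separated file with the columns
#' `gene score rank p_value direction n_outlier_samples outlier_samples`
#' (rank 1 = best; `outlier_samples` is a comma-joined sample ID list, empty
#' when none). Columns absent from `table` (e.g. comparator tables carry no
#' p-values) are filled with `NA` / empty fields.
#'
#' @param table A data frame with at least `gene`, `score` and `rank` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("gene", "score", "rank") %in% colnames(table)))
  out <- data.frame(
    gene = as.character(table$gene),
    score = table$score,
    rank = as.integer(table$rank),
    p_value = if ("p_value" %in% colnames(table)) table$p_value else NA_real_,
    direction = if ("direction" %in% colnames(table)) table$direction else NA_character_,
    n_outlier_samples = if ("n_outlier_samples" %in% colnames(table))
      as.integer(table$n_outlier_samples) else 0L,
    outlier_samples = if ("outlier_samples" %in% colnames(table))
      table$outlier_samples else "",
    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character", score = "numeric",
                                   rank = "integer", p_value = "numeric",
                                   direction = "character",
                                   n_outlier_samples = "integer",
                                   outlier_samples = "character"),
                    na.strings = "NA", quote = "", comment.char = "")
  tab$outlier_samples[is.na(tab$outlier_samples)] <- ""
  tab
}
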