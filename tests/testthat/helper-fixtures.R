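# fixtures built in code; no files are shipped

# small genes x samples matrix with named dims
rand_matrix <- function(m, n, seed = 1, n1 = max(2L, n %/% 3)) {
  set.seed(seed)
  x <- matrix(rnorm(m * n), m, n,
              dimnames = list(sprintf("g%03d", seq_len(m)),
                              sprintf("s%03d", seq_len(n))))
  list(x = x,
       labels = sample_labels(colnames(x)[seq_len(n1)],
                              colnames(x)[(n1 + 1):n]))
}

# the worked 8-sample transformation fixture: one ramp gene (1..8) with the
# last four samples as the cancer group, plus filler genes so leave-one-out
# scoring is defined
ramp_fixture <- function() {
  set.seed(99)
  x <- rbind(ramp = 1:8,
             matrix(rnorm(3 * 8), 3, 8,
                    dimnames = list(paste0("f", 1:3), NULL)))
  colnames(x) <- paste0("s", 1:8)
  list(x = x,
       labels = sample_labels(paste0("s", 5:8), paste0("s", 1:4)))
}

# brute-force evaluation of the score: explicit outer products and explicit
# row deletion, dense eigendecompositions only
brute_scores <- function(x, labels, group_energy = "mean") {
  tr <- ef_transform(x, labels)
  xh <- tr$values
  top_eig <- function(M) eigen(M, symmetric = TRUE, only.values = TRUE)$values[1]
  e_vec <- function(v) top_eig(v %*% t(v))
  s1 <- match(labels$s1, colnames(x))
  s2 <- match(labels$s2, colnames(x))
  vapply(seq_len(nrow(xh)), function(i) {
    e <- e_vec(xh[i, ])
    e1 <- e_vec(xh[i, s1])
    e2 <- e_vec(xh[i, s2])
    if (group_energy == "mean") {
      e1 <- e1 / length(s1); e2 <- e2 / length(s2)
    }
    d <- top_eig(tcrossprod(xh[-i, , drop = FALSE]))
    e * (e1 - e2) / d
  }, numeric(1))
}

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
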