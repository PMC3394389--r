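# Spectral energies. The rank-one energy of a vector v is the largest
# eigenvalue of the outer product v v^T, i.e. sum(v^2). The leave-one-out
# energy of gene i is the largest eigenvalue of X[-i,] %*% t(X[-i,]), equal
# to the top eigenvalue of the n x n Gram matrix G = t(X) %*% X downdated by
# the rank-one contribution of row i. The downdate is solved through the
# secular equation of G's eigendecomposition, so one dense n x n
# eigendecomposition serves every gene (O(n^2) per gene instead of a full
# decomposition per gene).

#' Rank-one spectral energy of a vector
#'
#' Largest eigenvalue of the outer-product matrix `v %*% t(v)`, which equals
#' the sum of squares of `v`.
#'
#' @param v Numeric vector with finite entries.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' rank1_energy(c(3, 4)) # 25
rank1_energy <- function(v) {
  if (!all(is.finite(v))) stop("v must be finite")
  sum(v^2)
}

# Top eigenvalues of G - x_i x_i^T for every row x_i of xhat, via the secular
# equation. By interlacing the top downdated eigenvalue lies in
# [lambda_2, lambda_1]; on that interval f(mu) = 1 - sum_j z_j^2/(lambda_j - mu)
# (z = V^T x_i) is strictly decreasing, so bisection is exact. When z is
# (numerically) orthogonal to the top eigenvector, lambda_1 survives the
# downdate unchanged.
loo_energies <- function(xhat) {
  m <- nrow(xhat)
  if (m < 2) stop("leave-one-out energy needs at least 2 retained genes")
  G <- crossprod(xhat)                    # n x n
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  n <- length(lam)
  Z2 <- (crossprod(eg$vectors, t(xhat)))^2  # n x m, squared secular weights
  out <- rep(lam[1], m)
  active <- Z2[1, ] > max(lam[1], 1) * 1e-13
  gap <- lam[1] - lam[2]
  if (any(active) && gap > 0) {
    idx <- which(active)
    lo <- rep(lam[2], length(idx))
    hi <- rep(lam[1], length(idx))
    W <- Z2[, idx, drop = FALSE]
    for (it in seq_len(80L)) {
      mu <- (lo + hi) / 2
      D <- lam - rep(mu, each = n)
      D[D == 0] <- .Machine$double.xmin
      f <- 1 - colSums(W / D)
      up <- f > 0
      lo[up] <- mu[up]
      hi[!up] <- mu[!up]
    }
    out[idx] <- (lo + hi) / 2
  }
  pmax(out, 0)
}

#' Leave-one-out spectral energy
#'
#' Largest eigenvalue of `(X[-i, ]) %*% t(X[-i, ])` for a transformed matrix,
#' i.e. the squared largest singular value of the matrix with gene `i`'s row
#' deleted. Computed by a rank-one downdate of the sample-space Gram matrix.
#'
#' @param transform An [ef_transform()] object with at least 2 retained genes.
#' @param gene Gene ID or row index of the gene to leave out.
#' @return A positive scalar.
#' @export
loo_energy <- function(transform, gene) {
  stopifnot(inherits(transform, "ef_transform"))
  i <- if (is.character(gene)) match(gene, transform$gene_ids) else as.integer(gene)
  if (is.na(i) || i < 1 || i > length(transform$gene_ids))
    stop("unknown gene: ", gene)
  loo_energies(transform$values)[i]
}
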