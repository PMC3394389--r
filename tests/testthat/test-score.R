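# fixed 5-gene x 8-sample integer fixture: the last four samples are the
# cancer group; "spike" carries u = 9 (the maximum of the other rows) added
# to two of the four cancer samples
score_fixture <- function() {
  x <- rbind(
    g1    = c(8, 1, 0, 5, 4, 4, 8, 5),
    g2    = c(3, 6, 4, 9, 4, 4, 0, 9),
    g3    = c(6, 1, 4, 6, 8, 1, 3, 9),
    g4    = c(0, 2, 9, 8, 8, 9, 2, 5),
    spike = c(3, 3, 3, 1, 3 + 9, 0 + 9, 0, 3))
  colnames(x) <- paste0("s", 1:8)
  list(x = x, labels = sample_labels(paste0("s", 5:8), paste0("s", 1:4)))
}

test_that("scores equal the brute-force dense-decomposition evaluation", {
  fx <- score_fixture()
  tab <- eigfusion_scores(fx$x, fx$labels)
  oracle <- brute_scores(fx$x, fx$labels)
  expect_equal(tab$score[match(rownames(fx$x), tab$gene)], oracle,
               tolerance = 1e-10)
  # the gene spiked in half of the cancer samples tops the ranking
  expect_identical(tab$gene[1], "spike")

  for (seed in 1:3) {
    rm <- rand_matrix(30, 12, seed = 200 + seed, n1 = 5)
    tab <- eigfusion_scores(rm$x, rm$labels)
    oracle <- brute_scores(rm$x, rm$labels)
    expect_equal(tab$score[match(rownames(rm$x), tab$gene)], oracle,
                 tolerance = 1e-8)
    # and the literal summed-group-energy form matches its own oracle
    tab2 <- eigfusion_scores(rm$x, rm$labels, group_energy = "sum")
    oracle2 <- brute_scores(rm$x, rm$labels, group_energy = "sum")
    expect_equal(tab2$score[match(rownames(rm$x), tab2$gene)], oracle2,
                 tolerance = 1e-8)
  }
})

test_that("a gene with equal cancer and normal energies scores zero", {
  rm <- rand_matrix(6, 8, seed = 20, n1 = 4)
  x <- rm$x
  x["g001", ] <- c(1, 5, 2, 8, 1, 5, 2, 8) # S2 mirror of S1
  tab <- eigfusion_scores(x, rm$labels)
  expect_equal(tab$score[tab$gene == "g001"], 0)
})

test_that("scores are invariant under positive affine transforms of one gene", {
  rm <- rand_matrix(15, 10, seed = 21, n1 = 4)
  tab <- eigfusion_scores(rm$x, rm$labels)
  x2 <- rm$x
  x2["g007", ] <- 3.7 * x2["g007", ] + 11
  tab2 <- eigfusion_scores(x2, rm$labels)
  expect_equal(tab2$score[match(tab$gene, tab2$gene)], tab$score,
               tolerance = 1e-10)
  expect_identical(tab2$gene, tab$gene) # identical ranking
})

test_that("scores are exactly invariant under negating a gene's profile", {
  # deletions and amplifications are detected symmetrically: the transform is
  # odd under negation, so squared energies and every score are unchanged
  rm <- rand_matrix(20, 14, seed = 22, n1 = 6)
  tab <- eigfusion_scores(rm$x, rm$labels)
  x2 <- rm$x
  x2["g005", ] <- -x2["g005", ]
  tab2 <- eigfusion_scores(x2, rm$labels)
  expect_equal(tab2$score[match(tab$gene, tab2$gene)], tab$score,
               tolerance = 1e-12)
})

test_that("tied scores keep input gene order and dropped genes are reported", {
  rm <- rand_matrix(8, 10, seed = 23, n1 = 4)
  x <- rbind(rm$x, dupA = rm$x["g002", ], dupB = rm$x["g002", ],
             flat = rep(1, 10))
  tab <- eigfusion_scores(x, rm$labels)
  expect_false("flat" %in% tab$gene)
  expect_identical(attr(tab, "dropped_genes")$gene_id, "flat")
  r <- setNames(tab$rank, tab$gene)
  expect_equal(tab$score[tab$gene == "dupA"], tab$score[tab$gene == "dupB"])
  expect_lt(r["g002"], r["dupA"]) # stable ties follow input order
  expect_lt(r["dupA"], r["dupB"])
  expect_identical(sort(tab$rank), seq_len(nrow(tab)))
  # score is non-increasing in rank
  expect_true(all(diff(tab$score[order(tab$rank)]) <= 0))
})

test_that("direction calls reflect the sign of the fence-exceeding values", {
  rm <- rand_matrix(10, 12, seed = 24, n1 = 6)
  x <- rm$x
  # crafted tight profiles so only the intended samples cross the fence
  base <- c(1.0, 1.2, 0.8, 1.1, 0.9, 1.05, 0.97, 1.13, 0.85, 1.08, 0.92, 1.03)
  x["g001", ] <- base + c(25, rep(0, 11))          # S1 up-outlier at s001
  x["g002", ] <- base - c(0, 25, rep(0, 10))       # S1 down-outlier at s002
  x["g003", ] <- base + c(0, 0, 25, -25, rep(0, 8)) # both directions
  tab <- eigfusion_scores(x, rm$labels)
  d <- setNames(tab$direction, tab$gene)
  o <- setNames(tab$outlier_samples, tab$gene)
  expect_identical(unname(d[c("g001", "g002", "g003")]),
                   c("over", "under", "mixed"))
  expect_identical(unname(o["g001"]), "s001")
  expect_identical(unname(o["g002"]), "s002")
})

test_that("permutation p-values are deterministic, bounded and monotone", {
  rm <- rand_matrix(30, 12, seed = 25, n1 = 5)
  cfg <- run_config(n_permutations = 10, seed = 42)
  p1 <- permutation_pvalues(rm$x, rm$labels, cfg)
  p2 <- permutation_pvalues(rm$x, rm$labels, cfg)
  expect_identical(p1, p2)
  n_null <- 30 * 10
  expect_true(all(p1$p_value >= 1 / (1 + n_null)))
  expect_true(all(p1$p_value <= 1))
  # higher score never has a larger p-value (pooled null)
  byscore <- p1[order(-p1$score), ]
  expect_true(all(diff(byscore$p_value) >= 0))
  expect_identical(p1$significant, p1$p_value < cfg$p_threshold)
})
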