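# one gene whose overall median is 0 and raw MAD is 1, so the standardized
# profile equals the raw values: S1 = (0,0,0,0,10), S2 = (1,-1,1,-1,-1)
std_gene_fixture <- function() {
  x <- rbind(g1 = c(0, 0, 0, 0, 10, 1, -1, 1, -1, -1),
             g2 = c(2, 1, 3, 2, 1, 3, 2, 1, 3, 2))
  colnames(x) <- paste0("s", 1:10)
  list(x = x, labels = sample_labels(paste0("s", 1:5), paste0("s", 6:10)))
}

test_that("COPA is the interpolated percentile of standardized cancer values", {
  fx <- std_gene_fixture()
  tab <- copa_scores(fx$x, fx$labels, percentile = 80)
  # 80th percentile of (0,0,0,0,10): index 4.2 -> 0 + 0.2*10 = 2
  expect_equal(tab$score[tab$gene == "g1"], 2)
  flat <- fx$x; flat["g1", ] <- 0
  tab0 <- copa_scores(rbind(flat, g3 = rnorm(10)), fx$labels)
  expect_false("g1" %in% tab0$gene) # zero MAD dropped
})

test_that("OS sums the standardized exceedances over the profile fence", {
  fx <- std_gene_fixture()
  tab <- os_scores(fx$x, fx$labels)
  # hand fence: q25 = -0.75, q75 = 0.75, threshold 2.25 -> only the 10 exceeds
  expect_equal(tab$score[tab$gene == "g1"], 10)
  # no cancer value above the fence -> 0
  x2 <- fx$x; x2["g1", 5] <- 0
  tab2 <- os_scores(x2, fx$labels)
  expect_equal(tab2$score[tab2$gene == "g1"], 0)
  # raising the outlier strictly increases the statistic
  x3 <- fx$x; x3["g1", 5] <- 20
  tab3 <- os_scores(x3, fx$labels)
  expect_gt(tab3$score[tab3$gene == "g1"], tab$score[tab$gene == "g1"])
})

test_that("ORT scales by group deviations and fences on the normal group", {
  # S1 = (0, 6), S2 = (-1, 0, 1, 2): scale = 1.5, scaled fence = 1.5,
  # single exceedance (6 - 0.5)/1.5 = 11/3
  x <- rbind(g1 = c(0, 6, -1, 0, 1, 2), g2 = c(1, 2, 3, 1, 2, 3))
  colnames(x) <- paste0("s", 1:6)
  lab <- sample_labels(paste0("s", 1:2), paste0("s", 3:6))
  tab <- ort_scores(x, lab)
  expect_equal(tab$score[tab$gene == "g1"], 11 / 3)
  # S1 drawn from the same values as S2 and below the fence -> exactly 0
  xs <- rbind(g1 = c(0, 1, -1, 0, 1, 2), g2 = c(1, 2, 3, 1, 2, 3))
  colnames(xs) <- paste0("s", 1:6)
  expect_equal(ort_scores(xs, lab)$score[1], 0)
  # raising one cancer value above the fence strictly increases it
  x2 <- x; x2["g1", 1] <- 7
  expect_gt(ort_scores(x2, lab)$score[match("g1", ort_scores(x2, lab)$gene)],
            11 / 3)
})

test_that("GTI weights the outlier proportion by the robust exceedance", {
  fx <- std_gene_fixture()
  tab <- gti_scores(fx$x, fx$labels)
  # q75(S1) = 0, IQR = 0, outliers = (10); scale = max(|0|, 1) = 1
  # statistic = (1/5) * (10 - 0) / 1 = 2
  expect_equal(tab$score[tab$gene == "g1"], 2)
  # no outliers -> 0
  x2 <- fx$x; x2["g1", ] <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  expect_equal(gti_scores(x2, fx$labels)$score[1], 0)
  # doubling the exceedance increases the statistic
  x3 <- fx$x; x3["g1", 5] <- 20
  expect_gt(gti_scores(x3, fx$labels)$score[match("g1", gti_scores(x3, fx$labels)$gene)],
            tab$score[tab$gene == "g1"])
})

test_that("the KS statistic equals the brute-force maximum ECDF gap", {
  x <- rbind(g1 = c(1, 2, 3, 2, 3, 4),
             g2 = c(1, 2, 3, 1, 2, 3),
             g3 = c(5, 6, 7, 1, 2, 3))
  colnames(x) <- paste0("s", 1:6)
  lab <- sample_labels(paste0("s", 1:3), paste0("s", 4:6))
  tab <- ks_scores(x, lab)
  s <- setNames(tab$score, tab$gene)
  expect_equal(unname(s["g2"]), 0) # identical samples
  expect_equal(unname(s["g3"]), 1) # disjoint supports
  # brute-force ECDF gap for g1
  grid <- sort(unique(x["g1", ]))
  gap <- max(abs(vapply(grid, function(t)
    mean(x["g1", 1:3] <= t) - mean(x["g1", 4:6] <= t), numeric(1))))
  expect_equal(unname(s["g1"]), gap)
})

test_that("all comparator statistics are location/positive-scale invariant", {
  rm <- rand_matrix(12, 14, seed = 30, n1 = 6)
  x2 <- rm$x
  x2["g004", ] <- 2.5 * x2["g004", ] - 7
  fns <- list(copa = function(x) copa_scores(x, rm$labels),
              os = function(x) os_scores(x, rm$labels),
              ort = function(x) ort_scores(x, rm$labels),
              gti = function(x) gti_scores(x, rm$labels),
              ks = function(x) ks_scores(x, rm$labels))
  for (nm in names(fns)) {
    a <- fns[[nm]](rm$x)
    b <- fns[[nm]](x2)
    expect_equal(b$score[match(a$gene, b$gene)], a$score,
                 tolerance = 1e-10, label = nm)
    expect_identical(sort(a$rank), seq_len(nrow(a)))
  }
})

test_that("the dispatcher routes methods and honors the configuration", {
  rm <- rand_matrix(10, 10, seed = 31, n1 = 5)
  cfg <- run_config(copa_percentile = 90)
  a <- outlier_scores(rm$x, rm$labels, "copa", cfg)
  b <- copa_scores(rm$x, rm$labels, 90)
  expect_equal(a$score, b$score)
  expect_error(outlier_scores(rm$x, rm$labels, "sam"), "arg")
})
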