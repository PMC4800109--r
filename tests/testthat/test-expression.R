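small_matrix <- function(seed = 1, n_probes = 50, na = 4, nb = 5) {
  set.seed(seed)
  vals <- matrix(rnorm(n_probes * (na + nb), 7, 1), n_probes)
  expression_matrix(vals, rep(c("target-line", "wnt-active"), c(na, nb)))
}

test_that("identical class data selects nothing", {
  set.seed(2)
  vals <- matrix(rnorm(100 * 4, 7, 0.5), 100)
  x <- expression_matrix(cbind(vals, vals),
                         rep(c("target-line", "wnt-active"), each = 4))
  de <- differential_expression(x)
  expect_equal(sum(de$selected), 0)
  expect_true(all(de$p_adj >= de$p))
})

test_that("differential expression is antisymmetric in the classes", {
  x <- small_matrix(3)
  ab <- differential_expression(x, "target-line", "wnt-active")
  ba <- differential_expression(x, "wnt-active", "target-line")
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p, ba$p)
})

test_that("per-probe t statistics match the reference t-test", {
  x <- small_matrix(4)
  de <- differential_expression(x)
  for (i in c(1, 10, 25, 50)) {
    ht <- t.test(x$values[i, x$classes == "target-line"],
                 x$values[i, x$classes == "wnt-active"], var.equal = TRUE)
    expect_equal(de$t[i], unname(ht$statistic))
    expect_equal(de$p[i], ht$p.value)
  }
  # Welch switch
  dew <- differential_expression(x, var_equal = FALSE)
  htw <- t.test(x$values[1, x$classes == "target-line"],
                x$values[1, x$classes == "wnt-active"], var.equal = FALSE)
  expect_equal(dew$p[1], htw$p.value)
})

test_that("the BH step equals a brute-force ranking oracle", {
  set.seed(6)
  for (rep in 1:5) {
    p <- runif(20)^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
  x <- small_matrix(7, n_probes = 20)
  de <- differential_expression(x)
  expect_equal(de$p_adj, oracle_bh(de$p))
})

test_that("zero-variance probes get the documented p rule", {
  vals <- matrix(rnorm(8 * 3, 7, 1), 3, 8)
  vals[1, ] <- 5                        # flat everywhere: equal means
  vals[2, ] <- rep(c(2, 4), each = 4)   # flat per class, unequal means
  x <- expression_matrix(vals, rep(c("target-line", "wnt-active"), each = 4))
  expect_warning(de <- differential_expression(x), "zero within-class")
  expect_equal(de$p[1], 1)
  expect_equal(de$p[2], .Machine$double.xmin)
  expect_true(de$zero_variance[1] && de$zero_variance[2])
})

test_that("selection is monotone in the thresholds", {
  ge <- gen_expression(sim_config(expression = list(n_probes = 2000L,
                                                    n_de = 50L)), seed = 8)
  n_sel <- function(fc, a) sum(differential_expression(
    ge$matrix, fc_threshold = fc, alpha = a)$selected)
  expect_gte(n_sel(1.5, 0.05), n_sel(2.0, 0.05))
  expect_gte(n_sel(2.0, 0.05), n_sel(2.0, 0.01))
})

test_that("planted DE probes are recovered at controlled FDR", {
  ge <- gen_expression(seed = 9)
  de <- differential_expression(ge$matrix)
  sel <- de$probe[de$selected]
  tp <- sum(sel %in% ge$truth$de_probes)
  expect_gte(tp / length(ge$truth$de_probes), 0.9)
  expect_lte((length(sel) - tp) / max(length(sel), 1), 0.05)
})

test_that("probe collapsing keeps the strongest probe per gene", {
  res <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                    gene = c("G1", "G1", "G1", NA),
                    log2_fc = c(1.07, 1.58, -0.26, 2.0))
  g <- collapse_probes(res)
  expect_equal(nrow(g), 2)
  expect_equal(g$probe[g$gene == "G1" & !is.na(g$gene)], "p2")
  expect_equal(attr(g, "n_no_symbol"), 1)

  uniq <- data.frame(probe = c("p1", "p2"), gene = c("A", "B"),
                     log2_fc = c(1, 2))
  expect_equal(nrow(collapse_probes(uniq)), 2)
})

test_that("two identical samples merge at height zero", {
  vals <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  tr <- hcluster(vals)
  expect_equal(tr$height[1], 0)
  expect_true(same_merge(tr$merges[[1]], list(a = 1, b = 2)))
  expect_true(all(tr$height >= 0))
  expect_error(cut_clusters(tr, 4), "between 1 and")
})

test_that("merge sequence equals the naive explicit-centroid oracle", {
  set.seed(12)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    vals <- matrix(rnorm(8 * n), 8, n)
    tr <- hcluster(vals)
    or <- oracle_centroid_cluster(vals)
    expect_equal(tr$height, or$heights, tolerance = 1e-8)
    for (s in seq_len(n - 1))
      expect_true(same_merge(tr$merges[[s]], or$merges[[s]]))
  }
})

test_that("centroid merges conserve the size-weighted member mean", {
  set.seed(14)
  vals <- matrix(rnorm(6 * 8), 6, 8)
  tr <- hcluster(vals)
  # the distance the tree reports at each step must equal the euclidean
  # distance between the exact member means of the merged clusters
  for (s in seq_along(tr$merges)) {
    m <- tr$merges[[s]]
    ca <- rowMeans(vals[, m$a, drop = FALSE])
    cb <- rowMeans(vals[, m$b, drop = FALSE])
    expect_equal(tr$height[s], sqrt(sum((ca - cb)^2)), tolerance = 1e-8)
  }
})

test_that("three planted sample groups are recovered at the 3-cut", {
  cfg <- sim_config(expression = list(
    class_sizes = c("target-line" = 2L, "wnt-active" = 14L, "normal" = 3L),
    n_probes = 3000L, n_de = 150L, log2_shift = 1.0, sigma = 0.5))
  ge <- gen_expression(cfg, seed = 15)
  de_probes <- c(ge$truth$de_probes, ge$truth$normal_probes)
  tr <- hcluster(ge$matrix, probes = de_probes)
  cl <- cut_clusters(tr, 3)
  expect_equal(length(unique(cl)), 3)
  # partition matches the class labels exactly
  classes <- ge$matrix$classes
  expect_equal(length(unique(cl[classes == "target-line"])), 1)
  expect_equal(length(unique(cl[classes == "wnt-active"])), 1)
  expect_equal(length(unique(cl[classes == "normal"])), 1)
  expect_equal(length(unique(cl[!duplicated(classes)])), 3)
})

test_that("missing values are refused rather than imputed", {
  vals <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(expression_matrix(vals, c("a", "b")), "missing values")
})
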