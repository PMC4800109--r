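peak_fixture <- function(t_dig, t_undig, r_dig = 100, r_undig = 100) {
  data.frame(
    probe = rep(c("CMTM3", "ref1", "ref2"), 2),
    reaction = rep(c("dig", "undig"), each = 3),
    height = c(t_dig, r_dig, r_dig, t_undig, r_undig, r_undig),
    is_reference = rep(c(FALSE, TRUE, TRUE), 2))
}

test_that("dosage ratios follow the ratio-of-ratios formula", {
  expect_equal(compute_dm(peak_fixture(100, 100), "CMTM3"), 1.0)
  expect_equal(compute_dm(peak_fixture(0, 100), "CMTM3"), 0.0)
  expect_equal(compute_dm(peak_fixture(50, 100), "CMTM3"), 0.5)
  # reference summarised per reaction: halving the digested refs doubles D_m
  expect_equal(compute_dm(peak_fixture(50, 100, r_dig = 50), "CMTM3"), 1.0)
  expect_error(compute_dm(peak_fixture(50, 0), "CMTM3"), "assay failure")
  expect_error(compute_dm(peak_fixture(50, 100, r_dig = 0), "CMTM3"),
               "assay failure")
  expect_warning(compute_dm(peak_fixture(150, 100), "CMTM3"), "exceeds 1")
})

test_that("the technical threshold calls methylation with a tie rule", {
  expect_false(call_methylated(0.10))
  expect_true(call_methylated(0.30))
  expect_false(call_methylated(0.15))  # boundary -> unmethylated
  expect_equal(call_methylated(c(0, 0.149, 0.151, 1)),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("bisulfite concordance tables report discordant pairs", {
  mlpa <- data.frame(sample_id = c("a", "b", "c"), locus = "CMTM3",
                     methylated = c(TRUE, FALSE, TRUE))
  bis_ok <- data.frame(sample_id = c("a", "b", "c"), locus = "CMTM3",
                       call = c("C/T", "T/T", "C/C"))
  v <- validate_threshold(mlpa, bis_ok)
  expect_equal(v$concordance, 1)
  expect_equal(sum(v$table) - sum(diag(v$table)), 0)

  bis_bad <- bis_ok; bis_bad$call[2] <- "C/C"
  v2 <- validate_threshold(mlpa, bis_bad)
  expect_equal(sum(diag(v2$table)), 2)
  expect_true(any(grepl("b", unlist(v2$cells[["FALSE.TRUE"]]))))

  expect_error(validate_threshold(mlpa, bis_ok[1:2, ]), "different")
})

test_that("simulated mis-calls give the planted concordance rate", {
  set.seed(5)
  n <- 400
  truth <- runif(n) < 0.5
  flip <- runif(n) < 0.10
  mlpa <- data.frame(sample_id = sprintf("s%03d", 1:n), locus = "L",
                     methylated = xor(truth, flip))
  bis <- data.frame(sample_id = sprintf("s%03d", 1:n), locus = "L",
                    call = ifelse(truth, "C/T", "T/T"))
  v <- validate_threshold(mlpa, bis)
  expect_lt(abs(v$concordance - 0.9), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("hypermethylation thresholds are normal mean + 1 sample SD", {
  prof <- methylation_profiles(data.frame(
    sample_id = rep(c("n1", "n2", "n3"), 2),
    tissue = "normal", group = "Lynch", beta_catenin = "unknown",
    locus = rep(c("CMTM3", "DGKI"), each = 3),
    dm = c(0.1, 0.1, 0.1, 0.1, 0.2, 0.3)))
  thr <- fit_thresholds(prof)
  expect_equal(thr$threshold[thr$locus == "CMTM3"], 0.1)  # zero SD
  expect_equal(thr$threshold[thr$locus == "DGKI"], 0.3)   # 0.2 + 0.1
  expect_equal(thr$n_normals, c(3L, 3L))

  expect_error(fit_thresholds(prof[c(1, 4:6), ]), ">= 2 normal")
})

test_that("threshold fitting is order-invariant and scale-equivariant", {
  set.seed(7)
  base <- data.frame(
    sample_id = sprintf("n%03d", 1:50), tissue = "normal", group = "Lynch",
    beta_catenin = "unknown", locus = "CMTM3", dm = abs(rnorm(50, 0.1, 0.03)))
  t1 <- fit_thresholds(methylation_profiles(base))
  t2 <- fit_thresholds(methylation_profiles(base[sample(50), ]))
  expect_equal(t1$threshold, t2$threshold)
  scaled <- base; scaled$dm <- scaled$dm * 3
  t3 <- fit_thresholds(methylation_profiles(scaled))
  expect_equal(t3$threshold, 3 * t1$threshold)
})

test_that("burden counts locus exceedances and is monotone", {
  gc <- gen_methylation_cohort(seed = 21)
  thr <- fit_thresholds(gc$profiles)
  b <- hypermethylation_burden(gc$profiles, thr)
  expect_true(all(b$burden >= 0 & b$burden <= 7))
  expect_true(all(b$n_loci == 7))

  # direct per-locus comparison oracle
  tt <- gc$profiles[gc$profiles$tissue == "tumor", ]
  lk <- setNames(thr$threshold, thr$locus)
  oracle <- tapply(tt$dm > lk[tt$locus], tt$sample_id, sum)
  expect_equal(b$burden, as.integer(oracle[b$sample_id]),
               ignore_attr = TRUE)

  # raising one D_m never decreases the burden
  boosted <- gc$profiles
  i <- which(boosted$tissue == "tumor")[1]
  boosted$dm[i] <- 10
  b2 <- hypermethylation_burden(boosted, thr)
  expect_true(all(b2$burden >= b$burden))
  # raising thresholds never increases it
  thr_hi <- thr; thr_hi$threshold <- thr$threshold * 2
  b3 <- hypermethylation_burden(gc$profiles, thr_hi)
  expect_true(all(b3$burden <= b$burden))
})

test_that("group-specific hypermethylation frequencies are recovered", {
  # pattern of a Lynch-specific locus: 48% vs 8% vs 12% at n = 27/33/40
  strong <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    rates <- c(Lynch = 0.48, `sporadic-MSI` = 0.08, `sporadic-MSS` = 0.12)
    ns <- c(Lynch = 27L, `sporadic-MSI` = 33L, `sporadic-MSS` = 40L)
    rows <- do.call(rbind, lapply(names(ns), function(g)
      data.frame(sample_id = sprintf("%s%02d", g, seq_len(ns[[g]])),
                 tissue = "tumor", group = g, beta_catenin = "unknown",
                 locus = "KLK10",
                 dm = ifelse(runif(ns[[g]]) < rates[[g]], 0.5, 0.05))))
    thr <- data.frame(locus = "KLK10", mean = 0.08, sd = 0.03,
                      threshold = 0.11, n_normals = 110L)
    hf <- hypermethylation_frequency(methylation_profiles(rows), thr)
    f <- setNames(hf$frequencies$percent, hf$frequencies$group)
    expect_lt(abs(f[["Lynch"]] / 100 - 0.48), 3 * sqrt(0.48 * 0.52 / 27))
    p <- hf$comparisons$p[hf$comparisons$group_a == "Lynch" |
                          hf$comparisons$group_b == "Lynch"]
    expect_true(all(p < 0.05))
    if (any(p < 0.001)) strong <- strong + 1L
  }
  expect_gte(strong, 3)  # the Lynch excess is strongly significant
})

test_that("single-tumor groups are reported but not compared", {
  rows <- data.frame(
    sample_id = c("a", "b", "c"), tissue = "tumor",
    group = c("Lynch", "sporadic-MSI", "sporadic-MSI"),
    beta_catenin = "unknown", locus = "KLK10", dm = c(0.5, 0.05, 0.05))
  thr <- data.frame(locus = "KLK10", mean = 0.08, sd = 0.03,
                    threshold = 0.11, n_normals = 110L)
  expect_warning(hf <- hypermethylation_frequency(methylation_profiles(rows),
                                                  thr),
                 "single tumor")
  expect_equal(hf$frequencies$percent[hf$frequencies$group == "Lynch"], 100)
  expect_null(hf$comparisons)
})

test_that("burden-vs-catenin ANOVA behaves at both extremes", {
  mk <- function(bc, burdens) do.call(rbind, lapply(seq_along(burdens),
    function(i) data.frame(
      sample_id = sprintf("%s%02d", bc, i), tissue = "tumor",
      group = "sporadic-MSS", beta_catenin = bc,
      locus = c("CMTM3", "DGKI", "OPCML", "KLK10", "EPCAM",
                "DLC1", "DLC1_i4"),
      dm = c(rep(0.5, burdens[i]), rep(0.05, 7 - burdens[i])))))
  thr <- data.frame(locus = c("CMTM3", "DGKI", "OPCML", "KLK10", "EPCAM",
                              "DLC1", "DLC1_i4"),
                    mean = 0.08, sd = 0.03, threshold = 0.11,
                    n_normals = 110L)
  same <- methylation_profiles(rbind(mk("nuclear", c(2, 3, 2, 3)),
                                     mk("membranous", c(2, 3, 2, 3))))
  res <- burden_vs_catenin(same, thr)
  expect_equal(diff(res$means$mean_burden), 0)
  expect_equal(res$anova$p, 1)

  # with two groups, F equals the squared pooled t statistic
  set.seed(9)
  a <- rnorm(20, 3.6, 1.5); b <- rnorm(20, 2.8, 1.5)
  an <- anova_oneway(list(a, b))
  tt <- independent_t(a, b)
  expect_equal(an$F, tt$t^2)
  expect_equal(an$p, tt$p)
})

test_that("paired tumor-normal testing gates on normality", {
  set.seed(13)
  # identical pairs: nothing to reject
  eq <- data.frame(pair_id = 1:10, locus = "CMTM3",
                   tumor_dm = 0.1, normal_dm = 0.1)
  r1 <- paired_tumor_normal(eq)
  expect_equal(r1$p, 1)
  expect_equal(r1$test, "degenerate")

  # planted +0.3 shift over 30 pairs is detected
  sh <- data.frame(pair_id = 1:30, locus = "DGKI",
                   normal_dm = abs(rnorm(30, 0.1, 0.05)))
  sh$tumor_dm <- sh$normal_dm + 0.3 + rnorm(30, 0, 0.1)
  r2 <- paired_tumor_normal(sh)
  expect_lt(r2$p, 0.05)
  expect_true(r2$test %in% c("paired-t", "wilcoxon"))

  # grossly non-normal differences take the Wilcoxon branch
  nn <- data.frame(pair_id = 1:25, locus = "OPCML",
                   normal_dm = 0.1,
                   tumor_dm = 0.1 + c(rexp(25, 1)^3))
  r3 <- paired_tumor_normal(nn)
  expect_equal(r3$test, "wilcoxon")
})
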