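test_that("aneuploid index counts consistent gains and losses only", {
  normals <- lapply(1:10, function(i) meta_from_iscn("46,XX", i))
  expect_equal(aneuploid_index(normals, "XX"), 0)

  monoX <- lapply(1:10, function(i) meta_from_iscn("45,X", i))
  expect_equal(aneuploid_index(monoX, "XX"), 1)

  # a 50/50 split is cell-to-cell variability, not a consistent aneuploidy
  half <- c(lapply(1:5, function(i) meta_from_iscn("47,XX,+8", i)),
            lapply(6:10, function(i) meta_from_iscn("46,XX", i)))
  expect_equal(aneuploid_index(half, "XX"), 0)

  # deviation-weighted tetrasomy scores 2, cap-at-one scores 1
  tetra <- lapply(1:10, function(i) meta_from_iscn("48,XX,+8,+8", i))
  expect_equal(aneuploid_index(tetra, "XX"), 2)
  expect_equal(aneuploid_index(tetra, "XX", cap_at_one = TRUE), 1)

  expect_error(aneuploid_index(list(), "XX"), "at least one")
})

test_that("centromere variability averages per-label deviation percentages", {
  same <- lapply(1:20, function(i) meta_from_iscn("46,XX", i))
  expect_equal(centromere_variability(same, "XX"), 0)

  # one metaphase of twenty deviating at exactly one of 24 male labels
  one_dev_m <- c(lapply(1:19, function(i) meta_from_iscn("46,XY", i)),
                 list(meta_from_iscn("47,XY,+8", "m20")))
  expect_equal(centromere_variability(one_dev_m, "XY"), (100 / 20) / 24)

  # female baseline has 23 centromere classes
  one_dev_f <- c(lapply(1:19, function(i) meta_from_iscn("46,XX", i)),
                 list(meta_from_iscn("47,XX,+8", "m20")))
  expect_equal(centromere_variability(one_dev_f, "XX"), (100 / 20) / 23)

  expect_error(centromere_variability(same[1], "XX"), "at least two")
})

test_that("rearranged count filters by recurrence and excludes numerics", {
  normals <- lapply(1:20, function(i) meta_from_iscn("46,XX", i))
  expect_equal(rearranged_count(normals), 0)

  one_off <- c(lapply(1:19, function(i) meta_from_iscn("46,XX", i)),
               list(meta_from_iscn("46,XX,del(2)(p21)", "m20")))
  expect_equal(rearranged_count(one_off, 2), 0)
  expect_equal(rearranged_count(one_off, 1), 1)

  gains <- lapply(1:20, function(i) meta_from_iscn("47,XX,+8", i))
  expect_equal(rearranged_count(gains, 2), 0)

  expect_equal(rearranged_count(build_rko_metaphases(), 2), 14)
})

test_that("indices are monotone under added clonal gains", {
  set.seed(11)
  cfg <- sim_config(metaphase = list(clonal_events = c("del(2)(p21)"),
                                     numerical_rate = 0.2,
                                     structural_rate = 0.5))
  metas <- gen_metaphases(cfg, seed = 11)$metaphases
  ai0 <- aneuploid_index(metas, "XX")
  rc0 <- rearranged_count(metas, 2)
  plus7 <- parse_aberration("+7")
  metas2 <- lapply(metas, function(m) {
    m$aberrations <- c(m$aberrations, list(plus7))
    m$chromosome_count <- m$chromosome_count + 1L
    m
  })
  expect_equal(aneuploid_index(metas2, "XX"), ai0 + 1)
  expect_gte(rearranged_count(metas2, 2), rc0)
  # rearranged count is non-increasing in min_recurrence
  rcs <- vapply(1:6, function(r) rearranged_count(metas, r), numeric(1))
  expect_true(all(diff(rcs) <= 0))
})

test_that("indices match naive brute-force oracles on simulated populations", {
  for (s in 1:20) {
    cfg <- sim_config(metaphase = list(
      n_metaphases = 12L,
      clonal_events = c("+8", "del(2)(p21)", "+der(12)t(2;12)"),
      numerical_rate = 0.3, structural_rate = 0.7))
    metas <- gen_metaphases(cfg, seed = 100 + s)$metaphases
    expect_identical(aneuploid_index(metas, "XX"),
                     as.integer(oracle_aneuploid(metas, "XX")))
    expect_equal(centromere_variability(metas, "XX"),
                 oracle_variability(metas, "XX"))
    expect_identical(rearranged_count(metas, 2),
                     as.integer(oracle_rearranged(metas, 2)))
  }
})

test_that("CGH strings are parsed region by region", {
  rko <- paste("rev ish enh(7q21qter, 8q11qter, 9q22qter, 12pterq14,",
               "16q22qter, 20, 22), amp(8q22qter, 9q34qter)")
  res <- parse_cgh(rko)
  expect_equal(nrow(res), 9)
  expect_equal(sum(res$change_type == "enh"), 7)
  expect_equal(sum(res$change_type == "amp"), 2)

  expect_equal(nrow(parse_cgh("")), 0)

  mix <- parse_cgh("enh(1p), dim(3q), amp(8q24)")
  expect_equal(nrow(mix), 3)
  expect_setequal(mix$change_type, c("enh", "dim", "amp"))

  expect_error(parse_cgh("gain(1p)"), "unknown CGH change keyword")
  expect_error(parse_cgh("enh(99q)"), "invalid chromosome")
})

test_that("classification against reference ranges separates the two axes", {
  rr <- reference_ranges()
  rko <- classify_instability(instability_report(2, 1, 14, 9), rr)
  expect_equal(rko$numeric_class, "MSI-like")
  expect_equal(rko$structural_class, "MSS-like")

  msi <- classify_instability(instability_report(3, 2, 2, 2), rr)
  expect_equal(msi$numeric_class, "MSI-like")
  expect_equal(msi$structural_class, "MSI-like")

  odd <- classify_instability(instability_report(50, 80, 50, 50), rr)
  expect_equal(odd$numeric_class, "intermediate")
  expect_equal(odd$structural_class, "intermediate")

  detail <- attr(rko, "classification_detail")
  expect_true(all(detail$distance[detail$inside] == 0))
  expect_true(all(detail$distance >= 0))
})

test_that("mutation frequencies are reported as whole truncated percents", {
  tab <- tabulate_mutation_frequency(data.frame(
    group = c("sporadic-MSI", "sporadic-MSS", "Lynch"),
    positive = c(17L, 0L, 0L), tested = c(33L, 40L, 15L)))
  expect_equal(tab$percent, c(51, 0, 0))
  expect_error(tabulate_mutation_frequency(
    data.frame(group = "g", positive = 5, tested = 4)))
})
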