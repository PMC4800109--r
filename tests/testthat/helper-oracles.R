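# Independent brute-force oracles and shared fixtures.  Every oracle here
# recomputes its quantity from first principles (enumeration, explicit
# centroids, naive tallies) without touching the implementation path it
# checks.

rko_clone_string <- paste(
  "47 (44~49), XX, del(2)(p21), der(3)t(3;5), del(5q), dup(7)(q21q36),",
  "+der(8)t(8;8)(p12;q21), del(9), +der(12)t(2;12),",
  "+der(20)t(9;20)(q22;p13), and der(22)t(16;22)")

rko_extras <- list(
  list(token = "del(X)", recurrence = 2),
  list(token = "del(6p)", recurrence = 2),
  list(token = "der(12)t(5;12)", recurrence = 2),
  list(token = "der(10)t(2;10)(p21;q11)", recurrence = 2),
  list(token = "der(20)t(2;20)", recurrence = 2))

lim1215_string <- "46 (45–47), XY, del(3p), der(13)t(1;13)"

build_rko_metaphases <- function() {
  cl <- parse_iscn(rko_clone_string, n_metaphases = 14, total_metaphases = 20)
  expand_clone(cl, rko_extras)
}

# one metaphase built from an ISCN string
meta_from_iscn <- function(text, id = "m01") {
  cl <- parse_iscn(text)
  crc_meta(id, cl$modal_count, cl$sex_complement, cl$aberrations)
}

crc_meta <- function(id, count, sex, aberrations) {
  structure(list(id = id, chromosome_count = as.integer(count),
                 sex_complement = sex, aberrations = aberrations),
            class = "metaphase")
}

# ---- instability oracles: naive per-label tallies ------------------------

oracle_expected <- function(baseline_sex) {
  sx <- strsplit(baseline_sex, "")[[1]]
  labs <- c(as.character(1:22), intersect(c("X", "Y"), sx))
  e <- sapply(labs, function(l) {
    if (l %in% c("X", "Y")) sum(sx == l) else 2L
  })
  names(e) <- labs
  e
}

oracle_counts_matrix <- function(metas, baseline_sex) {
  exp <- oracle_expected(baseline_sex)
  sapply(metas, function(m) {
    cc <- centromere_counts(m, baseline_sex)
    v <- cc[names(exp)]
    v[is.na(v)] <- 0L
    v
  })
}

oracle_modal <- function(x, expected) {
  tab <- table(x)
  cand <- as.integer(names(tab))[tab == max(tab)]
  if (expected %in% cand) return(expected)
  d <- abs(cand - expected)
  cand <- cand[d == min(d)]
  min(cand)
}

oracle_aneuploid <- function(metas, baseline_sex) {
  cm <- oracle_counts_matrix(metas, baseline_sex)
  exp <- oracle_expected(baseline_sex)
  total <- 0L
  for (lab in names(exp))
    total <- total + abs(oracle_modal(cm[lab, ], exp[[lab]]) - exp[[lab]])
  total
}

oracle_variability <- function(metas, baseline_sex) {
  cm <- oracle_counts_matrix(metas, baseline_sex)
  exp <- oracle_expected(baseline_sex)
  pcts <- numeric(0)
  for (lab in names(exp)) {
    md <- oracle_modal(cm[lab, ], exp[[lab]])
    pcts <- c(pcts, 100 * sum(cm[lab, ] != md) / ncol(cm))
  }
  mean(pcts)
}

oracle_rearranged <- function(metas, min_recurrence) {
  seen <- character(0)
  for (m in metas) {
    ids <- character(0)
    for (a in m$aberrations)
      if (a$kind %in% c("del", "dup", "der", "iso", "add"))
        ids <- c(ids, paste(a$kind, a$primary,
                            paste(a$partners, collapse = ";"), a$band_spec))
    seen <- c(seen, unique(ids))
  }
  sum(table(seen) >= min_recurrence)
}

# ---- exact-test oracles ---------------------------------------------------

# two-sided Fisher by full enumeration over tables with fixed margins
oracle_fisher2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  pobs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(1, p)
}

# Benjamini-Hochberg by direct ranking definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cummin_rev <- rev(cummin(rev(m * p[o] / seq_len(m))))
  adj[o] <- pmin(cummin_rev, 1)
  adj
}

# ---- naive size-weighted centroid clustering ------------------------------

oracle_centroid_cluster <- function(vals) {
  n <- ncol(vals)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    cents <- sapply(clusters, function(mem)
      rowMeans(vals[, mem, drop = FALSE]))
    if (is.null(dim(cents))) cents <- matrix(cents, nrow = 1)
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq((i + 1L), length(clusters))) {
        d <- sqrt(sum((cents[, i] - cents[, j])^2))
        take <- d < best_d - 1e-12
        if (!take && abs(d - best_d) <= 1e-12) {
          cur <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          old <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
          take <- cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2])
        }
        if (take) { best <- c(i, j); best_d <- d }
      }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1L]] <-
      list(a = clusters[[best[1]]], b = clusters[[best[2]]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

same_merge <- function(m1, m2) {
  setequal(m1$a, m2$a) && setequal(m1$b, m2$b) ||
    setequal(m1$a, m2$b) && setequal(m1$b, m2$a)
}
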