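# Shared classical/exact tests used across the pipeline.  These are thin,
# validated surfaces over the base-R implementations; the test suite checks
# them against independent enumeration oracles.  Convention throughout:
# two-tailed p-values, alpha = 0.05.

#' Build and validate a 2x2 contingency table
#'
#' @param x Either a 2x2 matrix or the first of four cell counts (row-major:
#'   a, b, c, d).
#' @param b,c,d Remaining cell counts when `x` is scalar.
#' @param labels Optional list with `rows` and `cols` character vectors.
#' @return A 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(x, b = NULL, c = NULL, d = NULL, labels = NULL) {
  m <- if (is.matrix(x)) x else matrix(c(x, b, c, d), 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L))) stop("table must be 2x2")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("cells must be non-negative integers")
  storage.mode(m) <- "integer"
  if (!is.null(labels)) dimnames(m) <- labels
  structure(m, class = c("contingency_2x2", "matrix"))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-tailed p-value is the sum of the
#' probabilities of all tables (at fixed margins) whose point probability
#' does not exceed the observed table's.
#'
#' @param tab A `contingency_2x2` or plain 2x2 matrix.
#' @param two_tailed Two-tailed (default) or one-tailed ("greater") p.
#' @return P-value in [0, 1].
#' @export
fisher_exact <- function(tab, two_tailed = TRUE) {
  m <- unclass(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("cannot test a table with an empty margin")
  stats::fisher.test(m, alternative = if (two_tailed) "two.sided"
                                      else "greater")$p.value
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA.  With exactly two groups the F
#' statistic equals the square of the pooled two-sample t statistic.  Groups
#' that are identical throughout (zero between- and within-group variance)
#' return F = 0, p = 1.
#'
#' @param groups List of numeric vectors, each with >= 2 observations.
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 observations")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); n <- length(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - mean(y))^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0 && ssb == 0) return(list(F = 0, p = 1, df = c(k - 1L, n - k)))
  if (ssw == 0) return(list(F = Inf, p = 0, df = c(k - 1L, n - k)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       df = c(k - 1L, n - k))
}

#' Independent-samples t-test (two-tailed)
#'
#' @param a,b Numeric vectors.
#' @param var_equal Pooled-variance (default) or Welch.
#' @return List with `t`, `p`, `df`.
#' @export
independent_t <- function(a, b, var_equal = TRUE) {
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Paired-samples t-test (two-tailed)
#'
#' @param x,y Paired numeric vectors; or pass differences as `x` alone.
#' @return List with `t`, `p`, `df`.
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Wilcoxon signed-rank test (two-tailed)
#'
#' Exact null distribution for n <= `exact_limit` non-zero differences
#' (assuming no ties), normal approximation with continuity correction above.
#' Zero differences are dropped, as is conventional for the signed-rank test.
#'
#' @param x,y Paired numeric vectors; or pass differences as `x` alone.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return List with `V`, `p`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (length(d) == 0) return(list(V = 0, p = 1, exact = TRUE))
  use_exact <- length(d) <= exact_limit
  ht <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = TRUE))
  list(V = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}
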