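# Differential expression on a normalized log2 matrix and agglomerative
# clustering with size-weighted centroid linkage.

#' Assemble an expression matrix with class labels
#'
#' @param values Numeric matrix, probes x samples, log2 scale, no missing
#'   values (imputation is refused: NA input is an error).
#' @param classes Character vector of sample class labels
#'   ("target-line", "wnt-active", "normal"), named by or aligned with the
#'   matrix columns.
#' @param genes Optional character vector of gene symbols per probe
#'   (NA for probes without a symbol).
#' @return List of class `expression_matrix`.
#' @export
expression_matrix <- function(values, classes, genes = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(is.na(values)))
    stop("expression matrix contains missing values; imputation is refused")
  if (length(classes) != ncol(values))
    stop("one class label per sample required")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("p", seq_len(nrow(values)))
  if (!is.null(genes) && length(genes) != nrow(values))
    stop("one gene symbol (or NA) per probe required")
  structure(list(values = values,
                 classes = stats::setNames(as.character(classes),
                                           colnames(values)),
                 genes = genes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$classes)),
                            table(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Per-probe differential expression between two classes
#'
#' Unpaired t-test per probe on log2 values (pooled-variance by default,
#' Welch optional), Benjamini-Hochberg correction over all probes, linear
#' fold change `2^(meanA - meanB)`.  A probe is selected when its absolute
#' linear fold change reaches `fc_threshold` and its adjusted p-value is
#' below `alpha`.  Probes with zero variance in both classes get p = 1 when
#' the class means agree and the smallest representable p (flagged) when
#' they differ.
#'
#' @param x An `expression_matrix`.
#' @param class_a,class_b The two class labels to compare (A vs B; positive
#'   log2 fold change = higher in A).
#' @param fc_threshold Linear fold-change threshold (default 2.0).
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Data.frame with columns `probe`, `gene`, `log2_fc`, `fold_change`,
#'   `direction`, `t`, `p`, `p_adj`, `selected`, `zero_variance`.
#' @export
differential_expression <- function(x, class_a = "target-line",
                                    class_b = "wnt-active",
                                    fc_threshold = 2.0, alpha = 0.05,
                                    var_equal = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  a <- x$values[, x$classes == class_a, drop = FALSE]
  b <- x$values[, x$classes == class_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per compared class")

  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)

  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }

  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)

  zero_var <- se == 0
  equal_means <- abs(ma - mb) < .Machine$double.eps^0.5
  p[zero_var & equal_means] <- 1
  tstat[zero_var & equal_means] <- 0
  p[zero_var & !equal_means] <- .Machine$double.xmin
  tstat[zero_var & !equal_means] <- sign(ma - mb)[zero_var & !equal_means] * Inf
  if (any(zero_var & !equal_means))
    warning(sum(zero_var & !equal_means),
            " probe(s) with zero within-class variance but unequal means",
            call. = FALSE)

  p_adj <- stats::p.adjust(p, method = "BH")
  log2_fc <- ma - mb
  res <- data.frame(
    probe = rownames(x$values),
    gene = if (is.null(x$genes)) NA_character_ else x$genes,
    log2_fc = log2_fc,
    fold_change = 2^log2_fc,
    direction = ifelse(log2_fc >= 0, "up", "down"),
    t = tstat, p = p, p_adj = p_adj,
    selected = abs(log2_fc) >= log2(fc_threshold) & p_adj < alpha,
    zero_variance = zero_var,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Collapse probe-level results to gene level
#'
#' One record per gene symbol: the probe with the largest absolute log2 fold
#' change (first occurrence on ties).  Probes without a symbol are retained
#' as probe-level records and counted separately.
#'
#' @param results Data.frame from [differential_expression()].
#' @return Data.frame with one row per gene (plus symbol-less probes), with
#'   attribute `n_no_symbol`.
#' @export
collapse_probes <- function(results) {
  stopifnot(all(c("probe", "gene", "log2_fc") %in% names(results)))
  no_sym <- is.na(results$gene) | !nzchar(results$gene)
  with_sym <- results[!no_sym, , drop = FALSE]
  kept <- do.call(rbind, lapply(split(with_sym, with_sym$gene), function(d)
    d[which.max(abs(d$log2_fc)), , drop = FALSE]))
  out <- rbind(kept, results[no_sym, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_no_symbol") <- sum(no_sym)
  out
}

# tie-break helper: among tied minimal pairs, pick the one whose clusters
# contain the lowest original sample indices
pick_pair <- function(d2, active, min_member) {
  idx <- which(active)
  best <- NULL; best_d <- Inf
  for (ii in seq_len(length(idx) - 1L)) for (jj in seq((ii + 1L), length(idx))) {
    i <- idx[ii]; j <- idx[jj]
    dij <- d2[i, j]
    take <- FALSE
    if (dij < best_d - 1e-12) take <- TRUE
    else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
      cur <- sort(c(min_member[i], min_member[j]))
      old <- sort(c(min_member[best[1]], min_member[best[2]]))
      if (cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2]))
        take <- TRUE
    }
    if (take) { best <- c(i, j); best_d <- dij }
  }
  best
}

#' Agglomerative clustering with size-weighted centroid linkage
#'
#' Euclidean distance between cluster centroids; on merging, the new
#' centroid is the size-weighted mean of the two centroids (equivalently the
#' mean of all member samples), implemented through the Lance-Williams
#' update on squared distances.  Ties are broken deterministically toward
#' the pair containing the lowest original sample index.  Heights are
#' centroid-to-centroid euclidean distances (inversions are possible, as is
#' inherent to centroid linkage).
#'
#' @param x An `expression_matrix`, or a plain numeric matrix with samples
#'   in columns.
#' @param probes Optional probe subset (names or indices) to cluster on,
#'   e.g. the selected probes of [differential_expression()].
#' @return Object of class `centroid_hclust` with `merge`, `height`,
#'   `labels`, `order` (hclust-compatible) and `merges` (per-step member
#'   lists).
#' @export
hcluster <- function(x, probes = NULL) {
  vals <- if (inherits(x, "expression_matrix")) x$values else x
  stopifnot(is.matrix(vals))
  if (!is.null(probes)) vals <- vals[probes, , drop = FALSE]
  n <- ncol(vals)
  if (n < 2L) stop("need >= 2 samples to cluster")
  labels <- colnames(vals)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))

  d2 <- as.matrix(stats::dist(t(vals)))^2
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  min_member <- seq_len(n)
  members <- as.list(seq_len(n))
  node_id <- -seq_len(n)           # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merges <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    pr <- pick_pair(d2, active, min_member)
    i <- pr[1]; j <- pr[2]
    height[step] <- sqrt(max(d2[i, j], 0))
    merge[step, ] <- sort(c(node_id[i], node_id[j]))
    merges[[step]] <- list(a = members[[i]], b = members[[j]])

    ni <- size[i]; nj <- size[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        (ni * d2[k, i] + nj * d2[k, j]) / (ni + nj) -
        ni * nj * d2[i, j] / (ni + nj)^2
    }
    size[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    min_member[i] <- min(min_member[i], min_member[j])
    node_id[i] <- step
    active[j] <- FALSE
  }

  ord <- order_from_merge(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, merges = merges, n = n),
            class = "centroid_hclust")
}

order_from_merge <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) -node else c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' @export
print.centroid_hclust <- function(x, ...) {
  cat(sprintf("<centroid_hclust> %d samples, %d merges\n", x$n, x$n - 1L))
  invisible(x)
}

#' @export
as.hclust.centroid_hclust <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "weighted-centroid",
                 dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Cut a centroid-linkage tree into k clusters
#'
#' Replays the merge sequence until exactly `k` clusters remain (the cut is
#' by merge order, which is well defined even when centroid linkage produces
#' height inversions).  Cluster numbers are assigned by each cluster's
#' lowest sample index.
#'
#' @param tree A `centroid_hclust`.
#' @param k Number of clusters, 1 <= k <= n samples.
#' @return Integer vector of cluster labels named by sample.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "centroid_hclust"))
  n <- tree$n
  if (k < 1L || k > n) stop("k must be between 1 and the number of samples")
  cl <- seq_len(n)
  for (step in seq_len(n - k)) {
    m <- tree$merges[[step]]
    cl[cl %in% cl[c(m$a, m$b)]] <- min(cl[c(m$a, m$b)])
  }
  # renumber by lowest member index
  stats::setNames(match(cl, sort(unique(cl))), tree$labels)
}
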