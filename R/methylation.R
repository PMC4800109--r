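# MS-MLPA methylation analysis: dosage ratios, methylation calling against a
# technical threshold, normal-tissue-derived hypermethylation thresholds,
# per-tumor hypermethylation burden and its association with beta-catenin
# subcellular localization.
#
# D_m is the methylation dosage ratio of a locus: the target/reference peak
# ratio in the HhaI-digested reaction divided by the same ratio in the
# undigested reaction.  ~0 means the probed HhaI site is unmethylated
# (digestion destroys the target), ~1 fully methylated.

MLPA_LOCI <- c("CMTM3", "DGKI", "OPCML", "KLK10", "EPCAM", "DLC1", "DLC1_i4")

#' Methylation dosage ratio from an MS-MLPA peak table
#'
#' `D_m = (target_dig / ref_dig) / (target_undig / ref_undig)`, where
#' `ref_*` summarises the reference probes of the corresponding reaction
#' (mean by default, median as an alternative).
#'
#' @param peaks Data.frame for one sample with columns `probe`, `reaction`
#'   ("dig" or "undig"), `height` (>= 0), `is_reference` (logical).
#' @param locus Target probe name.
#' @param ref_summary "mean" (default) or "median" of the reference-probe
#'   peaks.
#' @return D_m value >= 0.  Values slightly above 1 are permitted and
#'   flagged with a warning.
#' @export
compute_dm <- function(peaks, locus, ref_summary = c("mean", "median")) {
  ref_summary <- match.arg(ref_summary)
  needed <- c("probe", "reaction", "height", "is_reference")
  if (!all(needed %in% names(peaks)))
    stop("peak table needs columns: ", paste(needed, collapse = ", "))
  if (any(peaks$height < 0)) stop("peak heights must be non-negative")
  summ <- if (ref_summary == "mean") mean else stats::median

  pick <- function(reaction, reference, probe = NULL) {
    rows <- peaks$reaction == reaction & peaks$is_reference == reference
    if (!is.null(probe)) rows <- rows & peaks$probe == probe
    peaks$height[rows]
  }
  t_dig <- pick("dig", FALSE, locus)
  t_undig <- pick("undig", FALSE, locus)
  r_dig <- summ(pick("dig", TRUE))
  r_undig <- summ(pick("undig", TRUE))
  if (length(t_dig) != 1L || length(t_undig) != 1L)
    stop("expected exactly one '", locus, "' peak per reaction")
  if (is.na(r_dig) || is.na(r_undig) || r_dig <= 0 || r_undig <= 0)
    stop("assay failure: no reference signal")
  if (t_undig <= 0)
    stop("assay failure: zero undigested target peak for ", locus)

  dm <- (t_dig / r_dig) / (t_undig / r_undig)
  if (dm > 1)
    warning("D_m = ", signif(dm, 3), " for ", locus,
            " exceeds 1 (flagged, kept)", call. = FALSE)
  dm
}

#' Call methylation against the technical detection threshold
#'
#' A locus is called methylated when its dosage ratio exceeds the technical
#' threshold (0.15 for all loci).  A value exactly at the threshold is
#' called unmethylated (documented tie rule; the bounding cases <0.15 and
#' >0.15 correspond to bisulfite T/T and C/T-or-C/C respectively).
#'
#' @param dm Numeric vector of dosage ratios.
#' @param technical_threshold Detection threshold, default 0.15.
#' @return Logical vector.
#' @export
call_methylated <- function(dm, technical_threshold = 0.15) {
  stopifnot(all(dm >= 0, na.rm = TRUE))
  dm > technical_threshold
}

#' Concordance of MS-MLPA methylation calls with bisulfite sequencing
#'
#' @param mlpa Data.frame with columns `sample_id`, `locus`, `methylated`
#'   (logical MS-MLPA call).
#' @param bisulfite Data.frame with columns `sample_id`, `locus`, `call`
#'   (one of "T/T", "C/T", "C/C"); T/T is unmethylated.
#' @return List with `table` (2x2 counts), `concordance` (fraction agreeing)
#'   and `cells` (per-cell sample/locus identifiers).
#' @export
validate_threshold <- function(mlpa, bisulfite) {
  key <- function(df) paste(df$sample_id, df$locus, sep = "::")
  if (!setequal(key(mlpa), key(bisulfite)) ||
      nrow(mlpa) != nrow(bisulfite))
    stop("MS-MLPA and bisulfite tables cover different sample/locus pairs")
  if (!all(bisulfite$call %in% c("T/T", "C/T", "C/C")))
    stop("bisulfite calls must be T/T, C/T or C/C")
  merged <- merge(mlpa, bisulfite, by = c("sample_id", "locus"))
  merged$bis_methylated <- merged$call != "T/T"
  lv <- c("unmethylated", "methylated")
  tab <- table(mlpa = factor(lv[merged$methylated + 1L], levels = lv),
               bisulfite = factor(lv[merged$bis_methylated + 1L], levels = lv))
  cells <- lapply(split(paste(merged$sample_id, merged$locus),
                        list(mlpa = merged$methylated,
                             bisulfite = merged$bis_methylated)),
                  identity)
  list(table = tab,
       concordance = sum(diag(tab)) / sum(tab),
       cells = cells)
}

#' Assemble a long-format methylation profile table
#'
#' @param df Data.frame with columns `sample_id`, `tissue` ("tumor" or
#'   "normal"), `group` ("Lynch", "sporadic-MSI", "sporadic-MSS"),
#'   `beta_catenin` ("nuclear", "membranous", "unknown"), `locus`, `dm`.
#' @return The validated data.frame, classed `methylation_profiles`.
#' @export
methylation_profiles <- function(df) {
  needed <- c("sample_id", "tissue", "group", "beta_catenin", "locus", "dm")
  if (!all(needed %in% names(df)))
    stop("need columns: ", paste(needed, collapse = ", "))
  stopifnot(all(df$tissue %in% c("tumor", "normal")),
            all(df$beta_catenin %in% c("nuclear", "membranous", "unknown")),
            all(df$dm >= 0))
  structure(df, class = c("methylation_profiles", "data.frame"))
}

#' Fit per-locus hypermethylation thresholds from normal tissue
#'
#' Threshold = mean + 1 sample standard deviation (n - 1 denominator) of the
#' normal-tissue dosage ratios at that locus.
#'
#' @param profiles A `methylation_profiles` table (tumor rows are ignored).
#' @return Data.frame of class `hypermethylation_thresholds` with columns
#'   `locus`, `mean`, `sd`, `threshold`, `n_normals`.
#' @export
fit_thresholds <- function(profiles) {
  normals <- profiles[profiles$tissue == "normal", , drop = FALSE]
  if (nrow(normals) == 0) stop("no normal-tissue profiles supplied")
  out <- do.call(rbind, lapply(split(normals, normals$locus), function(d) {
    if (nrow(d) < 2L)
      stop("need >= 2 normal samples per locus (", d$locus[1], " has ",
           nrow(d), ")")
    m <- mean(d$dm); s <- stats::sd(d$dm)
    data.frame(locus = d$locus[1], mean = m, sd = s, threshold = m + s,
               n_normals = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("hypermethylation_thresholds", "data.frame"))
}

threshold_lookup <- function(thresholds) {
  stats::setNames(thresholds$threshold, thresholds$locus)
}

#' Per-tumor hypermethylation burden
#'
#' The number of panel loci whose dosage ratio exceeds the locus's
#' normal-derived hypermethylation threshold, out of the loci measured for
#' that tumor.  Loci missing for a tumor reduce the denominator and are
#' reported in `n_loci`.
#'
#' @param tumors A `methylation_profiles` table (normal rows are ignored).
#' @param thresholds A `hypermethylation_thresholds` table.
#' @return Data.frame with one row per tumor: `sample_id`, `group`,
#'   `beta_catenin`, `burden`, `n_loci`.
#' @export
hypermethylation_burden <- function(tumors, thresholds) {
  tt <- tumors[tumors$tissue == "tumor", , drop = FALSE]
  thr <- threshold_lookup(thresholds)
  missing_loci <- setdiff(tt$locus, names(thr))
  if (length(missing_loci))
    stop("no threshold for locus/loci: ", paste(missing_loci, collapse = ", "))
  out <- do.call(rbind, lapply(split(tt, tt$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               beta_catenin = d$beta_catenin[1],
               burden = sum(d$dm > thr[d$locus]),
               n_loci = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-locus hypermethylation frequencies by patient group
#'
#' Fraction of tumors exceeding the locus threshold, per locus and group,
#' with pairwise two-tailed Fisher exact comparisons between groups.
#' Groups with a single tumor yield a frequency but their comparisons are
#' skipped with a warning.
#'
#' @param tumors A `methylation_profiles` table.
#' @param thresholds A `hypermethylation_thresholds` table.
#' @return List with `frequencies` (locus x group percentages and counts)
#'   and `comparisons` (pairwise Fisher p-values per locus).
#' @export
hypermethylation_frequency <- function(tumors, thresholds) {
  tt <- tumors[tumors$tissue == "tumor", , drop = FALSE]
  thr <- threshold_lookup(thresholds)
  tt$hyper <- tt$dm > thr[tt$locus]

  freq <- do.call(rbind, lapply(split(tt, list(tt$locus, tt$group),
                                      drop = TRUE), function(d)
    data.frame(locus = d$locus[1], group = d$group[1],
               n = nrow(d), n_hyper = sum(d$hyper),
               percent = 100 * mean(d$hyper), stringsAsFactors = FALSE)))
  rownames(freq) <- NULL

  comparisons <- list()
  for (loc in unique(tt$locus)) {
    dl <- tt[tt$locus == loc, ]
    gs <- unique(dl$group)
    if (length(gs) < 2L) next
    for (i in seq_len(length(gs) - 1L)) for (j in seq((i + 1L), length(gs))) {
      a <- dl[dl$group == gs[i], ]; b <- dl[dl$group == gs[j], ]
      if (nrow(a) < 2L || nrow(b) < 2L) {
        warning("skipping comparison at ", loc, ": group with a single tumor",
                call. = FALSE)
        next
      }
      tab <- contingency_2x2(sum(a$hyper), sum(!a$hyper),
                             sum(b$hyper), sum(!b$hyper))
      comparisons[[paste(loc, gs[i], "vs", gs[j])]] <-
        data.frame(locus = loc, group_a = gs[i], group_b = gs[j],
                   p = fisher_exact(tab), stringsAsFactors = FALSE)
    }
  }
  list(frequencies = freq,
       comparisons = if (length(comparisons))
         do.call(rbind, c(comparisons, make.row.names = FALSE)) else NULL)
}

#' Hypermethylation burden versus beta-catenin localization
#'
#' Mean burden per patient group x beta-catenin localization, plus a one-way
#' ANOVA of membranous versus nuclear tumors in the pooled sporadic series
#' (sporadic-MSI and sporadic-MSS combined).  Strata with fewer than 2
#' tumors are excluded from the means table with a warning.
#'
#' @param tumors A `methylation_profiles` table.
#' @param thresholds A `hypermethylation_thresholds` table.
#' @return List with `means` (group x localization), `anova`
#'   (F, p, df for pooled sporadic membranous vs nuclear) and `n`.
#' @export
burden_vs_catenin <- function(tumors, thresholds) {
  b <- hypermethylation_burden(tumors, thresholds)
  b <- b[b$beta_catenin %in% c("nuclear", "membranous"), , drop = FALSE]

  means <- do.call(rbind, lapply(split(b, list(b$group, b$beta_catenin),
                                       drop = TRUE), function(d) {
    if (nrow(d) < 2L) {
      warning("excluding stratum ", d$group[1], "/", d$beta_catenin[1],
              " with < 2 tumors", call. = FALSE)
      return(NULL)
    }
    data.frame(group = d$group[1], beta_catenin = d$beta_catenin[1],
               n = nrow(d), mean_burden = mean(d$burden),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL

  spor <- b[b$group %in% c("sporadic-MSI", "sporadic-MSS"), ]
  mem <- spor$burden[spor$beta_catenin == "membranous"]
  nuc <- spor$burden[spor$beta_catenin == "nuclear"]
  an <- if (length(mem) >= 2L && length(nuc) >= 2L)
    anova_oneway(list(membranous = mem, nuclear = nuc)) else NULL

  list(means = means, anova = an,
       n = c(membranous = length(mem), nuclear = length(nuc)))
}

#' Paired tumor-normal comparison of dosage ratios per locus
#'
#' For each locus, tests whether tumor D_m differs from the matched normal's.
#' The paired differences pass through a Shapiro-Wilk normality gate at
#' alpha = 0.05: normal-looking differences get a paired t-test, otherwise
#' the Wilcoxon signed-rank test.  The gate decision is reported per locus.
#'
#' @param pairs Data.frame with columns `pair_id`, `locus`, `tumor_dm`,
#'   `normal_dm`.
#' @param gate_alpha Normality-gate significance level (default 0.05).
#' @return Data.frame: `locus`, `n_pairs`, `mean_diff`, `test` ("paired-t",
#'   "wilcoxon" or "degenerate"), `shapiro_p`, `p`.
#' @export
paired_tumor_normal <- function(pairs, gate_alpha = 0.05) {
  needed <- c("pair_id", "locus", "tumor_dm", "normal_dm")
  if (!all(needed %in% names(pairs)))
    stop("need columns: ", paste(needed, collapse = ", "))
  out <- do.call(rbind, lapply(split(pairs, pairs$locus), function(d) {
    diff <- d$tumor_dm - d$normal_dm
    if (stats::sd(diff) == 0) {
      # identical pairs throughout: nothing to test
      return(data.frame(locus = d$locus[1], n_pairs = nrow(d),
                        mean_diff = mean(diff), test = "degenerate",
                        shapiro_p = NA_real_,
                        p = if (all(diff == 0)) 1 else NA_real_,
                        stringsAsFactors = FALSE))
    }
    sw <- stats::shapiro.test(diff)$p.value
    if (sw >= gate_alpha) {
      res <- paired_t(diff); test <- "paired-t"
    } else {
      res <- wilcoxon_signed_rank(diff); test <- "wilcoxon"
    }
    data.frame(locus = d$locus[1], n_pairs = nrow(d), mean_diff = mean(diff),
               test = test, shapiro_p = sw, p = res$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
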