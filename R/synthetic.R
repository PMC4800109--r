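# Seeded generators for every input the pipeline consumes, each returning
# its ground truth alongside the data.  Defaults mirror the study design
# the package models: 110 normal mucosa specimens; tumor groups of 27
# Lynch, 33 sporadic-MSI and 40 sporadic-MSS cancers; a 12 nuclear / 10
# membranous beta-catenin split in the LOH pilot; 20 metaphases per
# karyotyped line.  All randomness flows from R's RNG: call set.seed()
# (or use the `seed` argument) for reproducibility.

#' Simulation configuration with study-scale defaults
#'
#' Builds the nested parameter list the generators consume.  Overrides are
#' supplied as nested lists; unknown keys are rejected.
#'
#' @param ... Named overrides for the top-level sections `metaphase`,
#'   `methylation`, `marker`, `expression`, `seed`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(...) {
  defaults <- list(
    seed = 1L,
    metaphase = list(
      n_metaphases = 20L, baseline_sex = "XX",
      clonal_events = character(),
      numerical_rate = 0, structural_rate = 0),
    methylation = list(
      loci = MLPA_LOCI,
      normal_mean = 0.08, normal_sd = 0.03,
      n_normals = 110L,
      group_sizes = c("Lynch" = 27L, "sporadic-MSI" = 33L,
                      "sporadic-MSS" = 40L),
      membranous_fraction = 0.5,
      # planted mean hypermethylation burden (out of 7) per group x
      # beta-catenin localization
      burden_means = matrix(c(3.4, 3.1, 3.5, 2.7, 3.8, 2.9), 3, 2,
                            byrow = TRUE,
                            dimnames = list(c("Lynch", "sporadic-MSI",
                                              "sporadic-MSS"),
                                            c("membranous", "nuclear")))),
    marker = list(
      n_nuclear = 12L, n_membranous = 10L,
      n_dinucleotide = 31L, heterozygosity = 0.7,
      loh_prob = c(nuclear = 0.3, membranous = 0.3),
      instability_rate = 0.05),
    expression = list(
      n_probes = 10000L, n_de = 200L, log2_shift = 2,
      sigma = 0.5,
      class_sizes = c("target-line" = 6L, "wnt-active" = 6L,
                      "normal" = 0L)))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(over)) {
    if (is.list(defaults[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(bad))
        stop("unknown key(s) in '", nm, "': ", paste(bad, collapse = ", "))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  probs <- c(cfg$metaphase$numerical_rate, cfg$marker$heterozygosity,
             cfg$marker$loh_prob, cfg$marker$instability_rate,
             cfg$methylation$membranous_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic metaphase population with known ground truth
#'
#' Clonal events appear in every metaphase; per-metaphase random events are
#' layered on top: with probability `numerical_rate` a random whole-
#' chromosome gain or loss, and a Poisson(`structural_rate`) number of
#' random one-off deletions with unique band labels (so random structural
#' events are non-recurrent by construction).
#'
#' The returned truth holds the indices implied by the clonal events alone
#' (`aneuploid_index`, `n_rearranged`, and `centromere_variability = 0`);
#' with non-zero random rates the realized variability exceeds 0 and truth
#' fields reflecting randomness are set NA.
#'
#' @param cfg A `sim_config` (its `metaphase` section is used) or the
#'   section list itself.
#' @param seed Optional seed applied before generation.
#' @return List with `metaphases` and `truth`.
#' @export
gen_metaphases <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (inherits(cfg, "sim_config")) cfg$metaphase else cfg
  clonal <- lapply(p$clonal_events, parse_aberration)
  base <- baseline_count(p$baseline_sex)
  clonal_delta <- sum(vapply(clonal, function(a)
    if (a$kind == "num") a$delta else if (a$gain_prefix) 1L else 0L,
    integer(1)))

  metas <- lapply(seq_len(p$n_metaphases), function(i) {
    abs_i <- clonal
    delta <- clonal_delta
    if (stats::runif(1) < p$numerical_rate) {
      chrom <- sample(as.character(1:22), 1L)
      sgn <- sample(c("+", "-"), 1L)
      abs_i <- c(abs_i, list(parse_aberration(paste0(sgn, chrom))))
      delta <- delta + if (sgn == "+") 1L else -1L
    }
    n_str <- stats::rpois(1, p$structural_rate)
    if (n_str > 0) for (s in seq_len(n_str)) {
      chrom <- sample(as.character(1:22), 1L)
      band <- sprintf("q%02d", sample(10:40, 1L))
      abs_i <- c(abs_i, list(parse_aberration(
        sprintf("del(%s)(%sm%ds%d)", chrom, band, i, s))))
    }
    new_metaphase(sprintf("m%02d", i), base + delta, p$baseline_sex, abs_i)
  })

  random_free <- p$numerical_rate == 0 && p$structural_rate == 0
  clonal_structural <- unique(stats::na.omit(
    vapply(clonal, aberration_identity, character(1))))
  truth <- list(
    aneuploid_index = abs_clonal_index(clonal, p$baseline_sex),
    centromere_variability = if (random_free) 0 else NA_real_,
    n_rearranged = if (p$n_metaphases >= 2L) length(clonal_structural) else 0L,
    random_free = random_free)
  list(metaphases = metas, truth = truth)
}

# aneuploid index implied by a clonal event list alone
abs_clonal_index <- function(clonal, baseline_sex) {
  exp <- expected_counts(baseline_sex)
  delta <- stats::setNames(rep(0L, length(exp)), names(exp))
  for (a in clonal) {
    d <- if (a$kind == "num") a$delta else if (a$gain_prefix) 1L else 0L
    if (d != 0L) delta[a$primary] <- delta[a$primary] + d
  }
  sum(abs(delta))
}

# N(0,1) draw conditioned below `upper`, via inverse cdf
rnorm_below <- function(n, upper) {
  stats::qnorm(stats::runif(n) * stats::pnorm(upper))
}

#' Generate a synthetic MS-MLPA methylation cohort with known truth
#'
#' Normal-tissue dosage ratios are drawn per locus from a normal
#' distribution truncated at 0.  For each tumor and locus, the locus is
#' planted hypermethylated with probability `burden_mean / n_loci` for the
#' tumor's group and beta-catenin class; planted-hypermethylated loci draw
#' D_m well above the true threshold (mu + sigma), background loci draw
#' from the lower bulk of the normal distribution (below mu + 0.5 sigma),
#' so the planted exceedance probability is exact with respect to the
#' normal-derived threshold.
#'
#' @param cfg A `sim_config` (its `methylation` section is used) or the
#'   section list itself.
#' @param seed Optional seed applied before generation.
#' @return List with `profiles` (a [methylation_profiles()] table of normals
#'   and tumors) and `truth` (true thresholds, planted burden means,
#'   per-tumor planted burden).
#' @export
gen_methylation_cohort <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (inherits(cfg, "sim_config")) cfg$methylation else cfg
  loci <- p$loci; n_loci <- length(loci)
  mu <- rep_len(p$normal_mean, n_loci)
  sig <- rep_len(p$normal_sd, n_loci)
  names(mu) <- names(sig) <- loci

  normals <- do.call(rbind, lapply(seq_len(p$n_normals), function(i)
    data.frame(sample_id = sprintf("N%03d", i), tissue = "normal",
               group = names(p$group_sizes)[1 + (i %% length(p$group_sizes))],
               beta_catenin = "unknown", locus = loci,
               dm = pmax(stats::rnorm(n_loci, mu, sig), 0),
               stringsAsFactors = FALSE)))

  tumors <- list(); planted <- list()
  idx <- 0L
  for (g in names(p$group_sizes)) {
    ng <- p$group_sizes[[g]]
    n_mem <- round(ng * p$membranous_fraction)
    catenin <- rep(c("membranous", "nuclear"), c(n_mem, ng - n_mem))
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      bc <- catenin[i]
      p_hyper <- p$burden_means[g, bc] / n_loci
      hyper <- stats::runif(n_loci) < p_hyper
      dm <- numeric(n_loci)
      # hypermethylated: clearly above mu + sigma; background: lower bulk
      dm[hyper] <- mu[hyper] + sig[hyper] +
        abs(stats::rnorm(sum(hyper), 0.30, 0.08)) + 0.05
      dm[!hyper] <- pmax(mu[!hyper] +
                           sig[!hyper] * rnorm_below(sum(!hyper), 0.5), 0)
      sid <- sprintf("T%03d", idx)
      tumors[[sid]] <- data.frame(sample_id = sid, tissue = "tumor",
                                  group = g, beta_catenin = bc, locus = loci,
                                  dm = dm, stringsAsFactors = FALSE)
      planted[[sid]] <- data.frame(sample_id = sid, group = g,
                                   beta_catenin = bc,
                                   planted_burden = sum(hyper),
                                   stringsAsFactors = FALSE)
    }
  }
  profiles <- methylation_profiles(
    rbind(normals, do.call(rbind, c(tumors, make.row.names = FALSE))))
  list(profiles = profiles,
       truth = list(true_thresholds = mu + sig,
                    burden_means = p$burden_means,
                    planted = do.call(rbind, c(planted,
                                               make.row.names = FALSE))))
}

#' Generate a synthetic microsatellite marker cohort with known truth
#'
#' Bethesda markers plus `n_dinucleotide` synthetic dinucleotide markers
#' (names D<chr>S9<nnn>, labelled synthetic stand-ins for a genome-wide
#' marker panel).  Per sample and marker: heterozygous with probability
#' `heterozygosity`; heterozygous markers suffer LOH with the group's
#' per-marker probability (one allele's tumor signal reduced to ~30%);
#' with probability `instability_rate` the tumor shows novel alleles and is
#' excluded from LOH calling.
#'
#' @param cfg A `sim_config` (its `marker` section is used) or the section
#'   list itself.
#' @param seed Optional seed applied before generation.
#' @return List with `markers` (a [call_loh_table()]-ready table) and
#'   `truth` (planted LOH indicators).
#' @export
gen_marker_cohort <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (inherits(cfg, "sim_config")) cfg$marker else cfg
  dinuc <- sprintf("D%dS9%03d", rep_len(c(1:22), p$n_dinucleotide),
                   seq_len(p$n_dinucleotide))
  markers <- c(BETHESDA_MARKERS, dinuc)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(p$n_nuclear + p$n_membranous)),
    beta_catenin = rep(c("nuclear", "membranous"),
                       c(p$n_nuclear, p$n_membranous)),
    stringsAsFactors = FALSE)

  loh_prob <- p$loh_prob
  if (is.null(names(loh_prob)))
    loh_prob <- c(nuclear = loh_prob[1], membranous = loh_prob[1])

  rows <- list(); truth <- list()
  for (si in seq_len(nrow(samples))) for (mk in markers) {
    s <- samples[si, ]
    het <- stats::runif(1) < p$heterozygosity
    unstable <- stats::runif(1) < p$instability_rate
    h <- function() stats::rnorm(1, 1000, 100)
    if (!het) {
      n1 <- abs(h()); n2 <- NA_real_
      t1 <- abs(h()); t2 <- NA_real_
      loh <- FALSE
    } else {
      n1 <- abs(h()); n2 <- abs(h())
      loh <- !unstable && stats::runif(1) < loh_prob[[s$beta_catenin]]
      keep <- stats::rnorm(1, 1, 0.05)
      lose <- stats::rnorm(1, 0.30, 0.05)
      if (loh) {
        # lose one of the two alleles at random
        if (stats::runif(1) < 0.5) { t1 <- n1 * lose; t2 <- n2 * keep }
        else { t1 <- n1 * keep; t2 <- n2 * lose }
      } else {
        t1 <- n1 * stats::rnorm(1, 1, 0.05); t2 <- n2 * stats::rnorm(1, 1, 0.05)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s$sample_id, marker = mk, beta_catenin = s$beta_catenin,
      n1_height = n1, n2_height = n2, t1_height = t1, t2_height = t2,
      novel = unstable, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = s$sample_id, marker = mk, heterozygous = het,
      planted_loh = loh, unstable = unstable, stringsAsFactors = FALSE)
  }
  list(markers = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate a synthetic log2 expression matrix with planted DE probes
#'
#' Baseline log2 expression ~ N(7, 1) per probe; within-class noise
#' N(0, sigma).  `n_de` probes are planted differentially expressed in the
#' target-line class versus everything else, half up- and half
#' down-regulated by `log2_shift`.  When normals are requested they get
#' their own planted shift on a disjoint probe set of the same size, so the
#' three classes are mutually separable (the clustering scenario).
#'
#' @param cfg A `sim_config` (its `expression` section is used) or the
#'   section list itself.
#' @param seed Optional seed applied before generation.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (planted DE probe names and directions).
#' @export
gen_expression <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (inherits(cfg, "sim_config")) cfg$expression else cfg
  sizes <- p$class_sizes
  classes <- rep(names(sizes), sizes)
  n <- length(classes)
  probes <- sprintf("probe_%05d", seq_len(p$n_probes))
  genes <- sprintf("GENE%04d", 1L + ((seq_len(p$n_probes) - 1L) %/% 2L))
  genes[seq_len(p$n_probes) %% 17L == 0L] <- NA_character_  # symbol-less probes

  base <- stats::rnorm(p$n_probes, 7, 1)
  vals <- matrix(stats::rnorm(p$n_probes * n, 0, p$sigma), p$n_probes, n) + base
  colnames(vals) <- sprintf("%s_%02d", gsub("-", "", classes), seq_len(n))
  rownames(vals) <- probes

  de_idx <- seq_len(p$n_de)
  sign_up <- rep(c(1, -1), length.out = p$n_de)
  tgt <- classes == "target-line"
  vals[de_idx, tgt] <- vals[de_idx, tgt] + sign_up * p$log2_shift

  norm_idx <- integer()
  if (any(classes == "normal")) {
    norm_idx <- seq(p$n_de + 1L, 2L * p$n_de)
    nrm <- classes == "normal"
    vals[norm_idx, nrm] <- vals[norm_idx, nrm] +
      rep(c(1, -1), length.out = length(norm_idx)) * p$log2_shift
  }

  list(matrix = expression_matrix(vals, classes, genes),
       truth = list(de_probes = probes[de_idx],
                    de_direction = ifelse(sign_up > 0, "up", "down"),
                    normal_probes = probes[norm_idx]))
}
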