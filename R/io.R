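# Tab-separated readers/writers shared by all modules, pipeline
# configuration, and the end-to-end synthetic pipeline runner.
# All tables are UTF-8 TSV with a header row.

#' Write a table as TSV
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", fileEncoding = "UTF-8")
}

#' Read an MS-MLPA peak table
#'
#' Columns: `sample_id`, `reaction` ("dig"/"undig"), `probe`, `height`,
#' `is_reference` (logical or 0/1).
#' @param path File path.
#' @return Data.frame.
#' @export
read_peak_table <- function(path) {
  df <- read_tsv(path)
  needed <- c("sample_id", "reaction", "probe", "height", "is_reference")
  if (!all(needed %in% names(df)))
    stop("peak table needs columns: ", paste(needed, collapse = ", "))
  if (!all(df$reaction %in% c("dig", "undig")))
    stop("reaction must be 'dig' or 'undig'")
  df$is_reference <- as.logical(df$is_reference)
  df
}

#' Read an expression matrix TSV (probe id, optional gene symbol, samples)
#'
#' @param path File path; first column `probe`, optional second column
#'   `gene`, remaining columns one per sample.
#' @param classes Named character vector sample -> class label.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, classes) {
  df <- read_tsv(path)
  if (names(df)[1] != "probe") stop("first column must be 'probe'")
  has_gene <- names(df)[2] == "gene"
  genes <- if (has_gene) df$gene else NULL
  vals <- as.matrix(df[, -(1:(1 + has_gene)), drop = FALSE])
  rownames(vals) <- df$probe
  if (!all(colnames(vals) %in% names(classes)))
    stop("every sample column needs a class label")
  expression_matrix(vals, classes[colnames(vals)], genes)
}

#' Pipeline configuration
#'
#' Collects the analysis thresholds in one validated object: the MS-MLPA
#' technical detection threshold (0.15), the differential-expression fold
#' change (2.0) and significance (0.05) cut-offs, the LOH allele-ratio
#' bounds (0.5, 2.0) and the structural-recurrence minimum (2 metaphases),
#' plus the RNG seed.  Unknown keys are rejected.
#'
#' @param ... Overrides, or `file` pointing at a YAML file with the same
#'   keys.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(technical_threshold = 0.15, fc_threshold = 2.0,
                   alpha = 0.05, loh_bounds = c(0.5, 2.0),
                   min_recurrence = 2L, baseline_sex = "XX", seed = 1L)
  over <- list(...)
  if (!is.null(over$file)) {
    yml <- yaml::read_yaml(over$file)
    over$file <- NULL
    over <- utils::modifyList(yml, over)
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$technical_threshold >= 0, cfg$fc_threshold >= 1,
            cfg$alpha > 0, cfg$alpha < 1, length(cfg$loh_bounds) == 2L,
            cfg$min_recurrence >= 1L)
  structure(cfg, class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates synthetic inputs for the requested stages, runs each module on
#' them, and writes tab-separated reports plus a JSON run manifest (inputs,
#' package version, seed, thresholds) to `out_dir`.  All randomness flows
#' from the configured seed; rerunning with the same seed reproduces the
#' reports byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("karyotype", "methylation", "loh",
#'   "expression")`; empty vector writes the manifest only.
#' @param sim A [sim_config()] for the generators.
#' @return Invisible named list of report paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("karyotype", "methylation", "loh",
                                    "expression"),
                         sim = sim_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, c("karyotype", "methylation", "loh", "expression"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  paths <- list()

  if ("karyotype" %in% stages) {
    gm <- gen_metaphases(sim)
    rep_df <- data.frame(
      aneuploid_index = aneuploid_index(gm$metaphases,
                                        sim$metaphase$baseline_sex),
      centromere_variability =
        if (length(gm$metaphases) >= 2L)
          centromere_variability(gm$metaphases, sim$metaphase$baseline_sex)
        else NA_real_,
      n_rearranged = rearranged_count(gm$metaphases,
                                      config$min_recurrence))
    paths$karyotype <- write_tsv(rep_df, file.path(out_dir, "karyotype.tsv"))
  }

  if ("methylation" %in% stages) {
    gc <- gen_methylation_cohort(sim)
    thr <- fit_thresholds(gc$profiles)
    paths$thresholds <- write_tsv(thr, file.path(out_dir, "thresholds.tsv"))
    paths$burden <- write_tsv(
      hypermethylation_burden(gc$profiles, thr),
      file.path(out_dir, "burden.tsv"))
    freq <- hypermethylation_frequency(gc$profiles, thr)
    paths$methylation <- write_tsv(freq$frequencies,
                                   file.path(out_dir, "methylation_freq.tsv"))
  }

  if ("loh" %in% stages) {
    mk <- gen_marker_cohort(sim)
    calls <- call_loh_table(mk$markers, config$loh_bounds)
    paths$loh_calls <- write_tsv(calls, file.path(out_dir, "loh_calls.tsv"))
    paths$loh <- write_tsv(loh_frequency(calls)$by_marker,
                           file.path(out_dir, "loh_freq.tsv"))
  }

  if ("expression" %in% stages) {
    ge <- gen_expression(sim)
    de <- differential_expression(ge$matrix,
                                  fc_threshold = config$fc_threshold,
                                  alpha = config$alpha)
    paths$de <- write_tsv(de, file.path(out_dir, "de.tsv"))
  }

  manifest <- list(
    package = "crcprofiler",
    version = as.character(utils::packageVersion("crcprofiler")),
    stages = as.list(stages),
    seed = config$seed,
    thresholds = list(technical_threshold = config$technical_threshold,
                      fc_threshold = config$fc_threshold,
                      alpha = config$alpha,
                      loh_bounds = config$loh_bounds,
                      min_recurrence = config$min_recurrence),
    reports = lapply(paths, basename))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(paths)
}
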