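# Chromosomal-instability indices over metaphase sets, CGH change counting,
# and classification against reference ranges for classical MSI/MSS
# colorectal cancer cell lines.

counts_matrix <- function(metaphases, baseline_sex) {
  cc <- lapply(metaphases, centromere_counts, baseline_sex = baseline_sex)
  labels <- names(expected_counts(baseline_sex))
  m <- vapply(cc, function(x) {
    v <- x[labels]
    v[is.na(v)] <- 0L
    as.integer(v)
  }, integer(length(labels)))
  rownames(m) <- labels
  m
}

expected_counts <- function(baseline_sex) {
  labels <- c(as.character(1:22),
              intersect(c("X", "Y"), strsplit(baseline_sex, "")[[1]]))
  exp <- stats::setNames(rep(2L, length(labels)), labels)
  sx <- strsplit(baseline_sex, "")[[1]]
  exp["X"] <- sum(sx == "X")
  if ("Y" %in% labels) exp["Y"] <- sum(sx == "Y")
  exp
}

# modal count with ties broken toward `expected` (a 50/50 split is not a
# consistent aneuploidy), then toward the candidate closest to expected,
# then the smaller candidate
modal_count <- function(x, expected) {
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  if (expected %in% cand) return(expected)
  cand[order(abs(cand - expected), cand)][1]
}

#' Aneuploid index of a metaphase set
#'
#' The sum, over centromere classes, of the absolute difference between the
#' modal (cell-to-cell "consistent") centromere count and the expected
#' baseline count.  Each consistent monosomy or trisomy contributes 1; a
#' consistent tetrasomy contributes 2 by default (deviation-weighted), or 1
#' with `cap_at_one = TRUE` (event-counted).
#'
#' @param metaphases List of `metaphase` objects (>= 1).
#' @param baseline_sex Sex complement of the expected baseline, e.g. "XX".
#' @param cap_at_one Count each aneuploid chromosome once regardless of the
#'   copy-number deviation.
#' @return Non-negative integer.
#' @export
aneuploid_index <- function(metaphases, baseline_sex = "XX",
                            cap_at_one = FALSE) {
  if (length(metaphases) < 1L) stop("need at least one metaphase")
  m <- counts_matrix(metaphases, baseline_sex)
  exp <- expected_counts(baseline_sex)
  dev <- vapply(rownames(m), function(lab)
    abs(modal_count(m[lab, ], exp[[lab]]) - exp[[lab]]), numeric(1))
  if (cap_at_one) dev <- pmin(dev, 1)
  as.integer(sum(dev))
}

#' Centromere-number variability of a metaphase set
#'
#' For each centromere class, the percentage of metaphases whose centromere
#' count deviates from the modal count; the index is the unweighted mean of
#' these percentages over all centromere classes present in the baseline
#' (23 for a female baseline, 24 for a male one).
#'
#' @inheritParams aneuploid_index
#' @return Percentage in [0, 100].
#' @export
centromere_variability <- function(metaphases, baseline_sex = "XX") {
  if (length(metaphases) < 2L) stop("need at least two metaphases")
  m <- counts_matrix(metaphases, baseline_sex)
  exp <- expected_counts(baseline_sex)
  pct <- vapply(rownames(m), function(lab) {
    md <- modal_count(m[lab, ], exp[[lab]])
    100 * mean(m[lab, ] != md)
  }, numeric(1))
  mean(pct)
}

#' Structural identity of an aberration
#'
#' Kind + primary chromosome + translocation partners + band text; used to
#' decide whether two metaphases carry "the same" rearrangement.  Numerical
#' (`num`) and unrecognised (`other`) tokens have no structural identity.
#' @param a An `aberration`.
#' @return Character scalar or `NA`.
#' @export
aberration_identity <- function(a) {
  if (!(a$kind %in% c("del", "dup", "der", "iso", "add")))
    return(NA_character_)
  paste0(a$kind, "(", a$primary, ")",
         if (length(a$partners)) paste0("t(", paste(a$partners, collapse = ";"), ")") else "",
         if (nzchar(a$band_spec)) paste0("(", a$band_spec, ")") else "")
}

#' Recurrence-filtered count of rearranged chromosomes
#'
#' Counts distinct structural aberration identities present in at least
#' `min_recurrence` metaphases.  Whole-chromosome gains/losses are numerical,
#' not structural, and are excluded.
#'
#' @param metaphases List of `metaphase` objects.
#' @param min_recurrence Minimum number of metaphases an identity must appear
#'   in (default 2).
#' @return Non-negative integer.
#' @export
rearranged_count <- function(metaphases, min_recurrence = 2L) {
  stopifnot(min_recurrence >= 1L)
  per_meta <- lapply(metaphases, function(m) {
    ids <- vapply(m$aberrations, aberration_identity, character(1))
    unique(ids[!is.na(ids)])
  })
  tallies <- table(unlist(per_meta))
  sum(tallies >= min_recurrence)
}

#' Parse a CGH result string
#'
#' Accepts the "rev ish" notation, e.g.
#' `"rev ish enh(7q21qter, 8q11qter), amp(8q22qter)"`, or bare
#' `enh`/`dim`/`amp` lists.  Each comma-separated region inside a group is one
#' copy-number change.
#'
#' @param text CGH string; empty string gives zero changes.
#' @return Object of class `cgh_result`: a data.frame with columns
#'   `change_type`, `region`, `chromosome`.
#' @export
parse_cgh <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  txt <- sub("^rev\\s+ish\\s*", "", txt)
  empty <- data.frame(change_type = character(), region = character(),
                      chromosome = character(), stringsAsFactors = FALSE)
  if (!nzchar(txt)) return(structure(empty, class = c("cgh_result", "data.frame")))

  grp_re <- "([a-z]+)\\(([^()]*)\\)"
  groups <- regmatches(txt, gregexpr(grp_re, txt))[[1]]
  leftover <- txt
  for (g in groups) leftover <- sub(g, "", leftover, fixed = TRUE)
  if (grepl("[^,[:space:]]", leftover))
    stop("unparseable CGH text near: '", trimws(leftover), "'")
  if (length(groups) == 0) stop("no change groups found in: '", text, "'")

  rows <- lapply(groups, function(g) {
    m <- regmatches(g, regexec(grp_re, g))[[1]]
    kw <- m[2]
    if (!(kw %in% c("enh", "dim", "amp")))
      stop("unknown CGH change keyword '", kw, "'")
    regions <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    regions <- regions[nzchar(regions)]
    chrom <- sub("^([0-9]{1,2}|X|Y).*$", "\\1", regions)
    bad <- setdiff(chrom, CHROM_LABELS)
    if (length(bad))
      stop("invalid chromosome in CGH region(s): ",
           paste(regions[chrom %in% bad], collapse = ", "))
    data.frame(change_type = kw, region = regions, chromosome = chrom,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("cgh_result", "data.frame"))
}

#' Reference ranges for instability indices of MSI vs MSS cell lines
#'
#' Literature-derived ranges and means of the four instability indices for
#' classical microsatellite-unstable (MSI) and microsatellite-stable (MSS)
#' colorectal cancer cell lines.  Shipped as a tab-separated config file; a
#' different file with the same columns can be supplied.
#'
#' @param path TSV with columns `index`, `class`, `min`, `max`, `mean`
#'   (default: the file shipped with the package).
#' @return Data.frame of class `reference_ranges`.
#' @export
reference_ranges <- function(path = system.file("extdata",
                                                "reference_ranges.tsv",
                                                package = "crcprofiler")) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("index", "class", "min", "max", "mean")
  if (!all(needed %in% names(df)))
    stop("reference ranges file needs columns: ", paste(needed, collapse = ", "))
  if (any(df$min > df$mean | df$mean > df$max))
    stop("reference ranges must satisfy min <= mean <= max")
  structure(df, class = c("reference_ranges", "data.frame"))
}

#' Assemble an instability report
#'
#' @param aneuploid_index,centromere_variability,n_rearranged,n_cgh_changes
#'   The four index values for one cell line.
#' @return Object of class `instability_report`.
#' @export
instability_report <- function(aneuploid_index, centromere_variability,
                               n_rearranged, n_cgh_changes) {
  stopifnot(aneuploid_index >= 0, centromere_variability >= 0,
            centromere_variability <= 100, n_rearranged >= 0,
            n_cgh_changes >= 0)
  structure(list(aneuploid_index = aneuploid_index,
                 centromere_variability = centromere_variability,
                 n_rearranged = n_rearranged,
                 n_cgh_changes = n_cgh_changes,
                 numeric_class = NA_character_,
                 structural_class = NA_character_),
            class = "instability_report")
}

range_vote <- function(value, ranges, index) {
  r <- ranges[ranges$index == index, ]
  inside <- r$min <= value & value <= r$max
  dist <- ifelse(inside, 0, pmin(abs(value - r$min), abs(value - r$max)))
  cls <- r$class[inside]
  vote <- if (length(cls) == 1L) cls else "intermediate"
  list(vote = vote,
       detail = data.frame(index = index, value = value, class = r$class,
                           inside = inside, distance = dist,
                           stringsAsFactors = FALSE))
}

axis_class <- function(votes) {
  v <- setdiff(unique(votes), "intermediate")
  if (length(v) == 1L) paste0(v, "-like") else "intermediate"
}

#' Classify a cell line as MSI-like or MSS-like on each instability axis
#'
#' The numeric axis uses the aneuploid index and centromere variability; the
#' structural axis uses the rearranged-chromosome and CGH change counts.  A
#' value inside exactly one class range votes for that class; inside both or
#' neither it votes "intermediate".  An axis whose non-intermediate votes all
#' agree gets that class; conflicting or all-intermediate votes give
#' "intermediate".  A per-index distance-to-range table accompanies the call.
#'
#' @param report An `instability_report`.
#' @param ranges A `reference_ranges` table (default: shipped values).
#' @return The report with `numeric_class` and `structural_class` filled and
#'   a `classification_detail` attribute.
#' @export
classify_instability <- function(report, ranges = reference_ranges()) {
  stopifnot(inherits(report, "instability_report"))
  vs <- list(
    ai  = range_vote(report$aneuploid_index, ranges, "aneuploid_index"),
    cv  = range_vote(report$centromere_variability, ranges,
                     "centromere_variability"),
    re  = range_vote(report$n_rearranged, ranges, "n_rearranged"),
    cgh = range_vote(report$n_cgh_changes, ranges, "n_cgh_changes"))
  report$numeric_class <- axis_class(c(vs$ai$vote, vs$cv$vote))
  report$structural_class <- axis_class(c(vs$re$vote, vs$cgh$vote))
  attr(report, "classification_detail") <-
    do.call(rbind, lapply(vs, `[[`, "detail"))
  report
}

#' @export
print.instability_report <- function(x, ...) {
  cat("<instability_report>\n")
  cat(sprintf("  aneuploid index:          %s\n", x$aneuploid_index))
  cat(sprintf("  centromere variability:   %.4g\n", x$centromere_variability))
  cat(sprintf("  rearranged chromosomes:   %s\n", x$n_rearranged))
  cat(sprintf("  CGH copy-number changes:  %s\n", x$n_cgh_changes))
  if (!is.na(x$numeric_class))
    cat(sprintf("  class: numeric %s, structural %s\n", x$numeric_class,
                x$structural_class))
  invisible(x)
}

#' Mutation-frequency tabulation
#'
#' Whole-percent mutation frequencies per tumor group.  Percentages are
#' truncated toward zero (so 17/33 reports 51, the convention of
#' whole-percent frequency tables).
#'
#' @param counts Data.frame with columns `group`, `positive`, `tested` (and
#'   optionally `not_available`).
#' @return The input with `percent` added.
#' @export
tabulate_mutation_frequency <- function(counts) {
  needed <- c("group", "positive", "tested")
  if (!all(needed %in% names(counts)))
    stop("need columns: ", paste(needed, collapse = ", "))
  stopifnot(all(counts$positive >= 0), all(counts$tested > 0),
            all(counts$positive <= counts$tested))
  counts$percent <- trunc(100 * counts$positive / counts$tested)
  counts
}
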