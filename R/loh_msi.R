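# Bethesda-panel microsatellite-instability classification and loss-of-
# heterozygosity calling at dinucleotide markers.

BETHESDA_MARKERS <- c("BAT25", "BAT26", "D5S346", "D2S123", "D17S250")

#' Classify MSI status from Bethesda-panel instability flags
#'
#' MSI-H when two or more markers are unstable, or when BAT25 or BAT26 is
#' unstable alone; otherwise not-MSI-H.  Missing markers reduce the tested
#' set and are reported in the result.
#'
#' @param unstable Named logical vector over Bethesda markers (names from
#'   `BAT25`, `BAT26`, `D5S346`, `D2S123`, `D17S250`); markers absent from
#'   the vector were not tested.
#' @return List with `status` ("MSI-H" or "not-MSI-H"), `n_unstable`,
#'   `n_tested`, `missing`.
#' @export
msi_classify <- function(unstable) {
  if (length(unstable) < 1L) stop("need at least one marker result")
  if (is.null(names(unstable)) || any(!nzchar(names(unstable))))
    stop("instability flags must be named by marker")
  unknown <- setdiff(names(unstable), BETHESDA_MARKERS)
  if (length(unknown))
    stop("not Bethesda-panel markers: ", paste(unknown, collapse = ", "))
  n_unstable <- sum(unstable)
  bat_unstable <- function(mk)
    mk %in% names(unstable) && isTRUE(unname(unstable[mk]))
  msi_h <- n_unstable >= 2L || bat_unstable("BAT25") || bat_unstable("BAT26")
  list(status = if (msi_h) "MSI-H" else "not-MSI-H",
       n_unstable = n_unstable, n_tested = length(unstable),
       missing = setdiff(BETHESDA_MARKERS, names(unstable)))
}

#' Call loss of heterozygosity at one marker
#'
#' For a tumor/normal pair at a microsatellite marker: non-informative if the
#' normal is homozygous; excluded-unstable if the tumor shows novel alleles
#' (microsatellite instability confounds the allele ratio); otherwise the
#' allele ratio `r = (T1/T2) / (N1/N2)` is formed with alleles ordered by
#' size, and LOH is called when `r <= lower` or `r >= upper` (default 0.5
#' and 2.0, i.e. at least a 50% relative loss of one allele's signal;
#' boundary values count as LOH).
#'
#' @param normal_heights Numeric vector of 1 (homozygous) or 2 germline
#'   allele peak heights, ordered by allele size.
#' @param tumor_heights Matching tumor allele peak heights (required unless
#'   the normal is homozygous).
#' @param novel_tumor_alleles Logical: tumor shows alleles absent from the
#'   germline.
#' @param bounds Length-2 numeric, the LOH ratio bounds (lower, upper).
#' @return List of class `loh_call` with `call` ("LOH", "retained",
#'   "non-informative", "excluded-unstable") and `allele_ratio` (or NA).
#' @export
call_loh <- function(normal_heights, tumor_heights = NULL,
                     novel_tumor_alleles = FALSE, bounds = c(0.5, 2)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  if (length(normal_heights) < 1L || length(normal_heights) > 2L)
    stop("expected 1 or 2 germline alleles")
  if (any(normal_heights <= 0)) stop("allele heights must be positive")
  res <- function(call, ratio = NA_real_)
    structure(list(call = call, allele_ratio = ratio), class = "loh_call")

  if (length(normal_heights) == 1L) return(res("non-informative"))
  if (isTRUE(novel_tumor_alleles)) return(res("excluded-unstable"))
  if (is.null(tumor_heights) || length(tumor_heights) != 2L ||
      any(is.na(tumor_heights)))
    stop("missing tumor allele data at an informative marker")
  if (any(tumor_heights < 0)) stop("allele heights must be non-negative")

  r <- (tumor_heights[1] / tumor_heights[2]) /
       (normal_heights[1] / normal_heights[2])
  call <- if (r <= bounds[1] || r >= bounds[2]) "LOH" else "retained"
  res(call, r)
}

#' @export
print.loh_call <- function(x, ...) {
  cat("<loh_call>", x$call,
      if (!is.na(x$allele_ratio)) sprintf("(r = %.3g)", x$allele_ratio),
      "\n")
  invisible(x)
}

#' Call LOH over a marker table
#'
#' @param markers Data.frame with columns `sample_id`, `marker`,
#'   `beta_catenin`, `n1_height`, `n2_height` (NA when homozygous),
#'   `t1_height`, `t2_height`, `novel` (logical).
#' @param bounds LOH ratio bounds, passed to [call_loh()].
#' @return The input with `call` and `allele_ratio` columns added.
#' @export
call_loh_table <- function(markers, bounds = c(0.5, 2)) {
  needed <- c("sample_id", "marker", "n1_height", "n2_height",
              "t1_height", "t2_height", "novel")
  if (!all(needed %in% names(markers)))
    stop("need columns: ", paste(needed, collapse = ", "))
  calls <- lapply(seq_len(nrow(markers)), function(i) {
    r <- markers[i, ]
    nh <- c(r$n1_height, r$n2_height); nh <- nh[!is.na(nh)]
    th <- c(r$t1_height, r$t2_height)
    call_loh(nh, if (all(is.na(th))) NULL else th, isTRUE(r$novel),
             bounds = bounds)
  })
  markers$call <- vapply(calls, `[[`, character(1), "call")
  markers$allele_ratio <- vapply(calls, `[[`, numeric(1), "allele_ratio")
  markers
}

#' Per-locus LOH frequencies, overall and by beta-catenin status
#'
#' Frequency = LOH calls / informative calls (LOH + retained) per marker.
#' Markers above 50% overall are flagged as high-frequency; group
#' differences are tested per marker by two-tailed Fisher exact.  Markers
#' with zero informative cases get an undefined (NA) frequency and are
#' excluded from comparisons.
#'
#' @param calls Data.frame as returned by [call_loh_table()], with a
#'   `beta_catenin` column ("nuclear"/"membranous").
#' @param flag_above Overall-frequency flag threshold (default 0.5).
#' @return List with `by_marker` (overall and per-group fractions, flag,
#'   Fisher p) and `n_informative`.
#' @export
loh_frequency <- function(calls, flag_above = 0.5) {
  stopifnot(all(c("marker", "call") %in% names(calls)))
  has_groups <- "beta_catenin" %in% names(calls)
  rows <- lapply(split(calls, calls$marker), function(d) {
    inf <- d[d$call %in% c("LOH", "retained"), ]
    overall <- if (nrow(inf) == 0) NA_real_ else mean(inf$call == "LOH")
    out <- data.frame(marker = d$marker[1], n_informative = nrow(inf),
                      frac_loh = overall,
                      high_frequency = !is.na(overall) && overall > flag_above,
                      stringsAsFactors = FALSE)
    if (has_groups) {
      for (g in c("nuclear", "membranous")) {
        gi <- inf[inf$beta_catenin == g, ]
        out[[paste0("frac_", g)]] <-
          if (nrow(gi) == 0) NA_real_ else mean(gi$call == "LOH")
      }
      nuc <- inf[inf$beta_catenin == "nuclear", ]
      mem <- inf[inf$beta_catenin == "membranous", ]
      tab <- matrix(c(sum(nuc$call == "LOH"), sum(nuc$call == "retained"),
                      sum(mem$call == "LOH"), sum(mem$call == "retained")),
                    2, 2, byrow = TRUE)
      out$fisher_p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        fisher_exact(contingency_2x2(tab)) else NA_real_
    }
    out
  })
  by_marker <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(by_marker = by_marker,
       n_informative = sum(by_marker$n_informative))
}
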