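# ISCN-style karyotype parsing and per-chromosome centromere accounting.
#
# The supported dialect is deliberately small: a modal-count prefix with an
# optional range, a sex complement, structural tokens del/dup/der(+t)/iso/add,
# and bare whole-chromosome gains/losses (+8, -Y).  Anything else is kept
# verbatim with kind "other" and reported, never dropped.

CHROM_LABELS <- c(as.character(1:22), "X", "Y")

#' Parse a single ISCN aberration token
#'
#' Recognised forms: `del(2)(p21)`, `del(5q)`, `del(9)`, `dup(7)(q21q36)`,
#' `der(3)t(3;5)`, `+der(8)t(8;8)(p12;q21)`, `iso(17)(q10)`, `add(19)(p13)`,
#' and bare whole-chromosome tokens `+8` / `-Y`.  Unrecognised tokens are
#' preserved with `kind = "other"` and a warning.
#'
#' @param token Character scalar, one aberration token.
#' @return An object of class `aberration`: a list with fields `raw`, `kind`
#'   (one of del, dup, der, iso, add, num, other), `gain_prefix`, `delta`
#'   (+1/-1 copy-number effect for `num` tokens, else 0), `primary`
#'   (chromosome carrying the centromere), `partners` (translocation
#'   partners, possibly empty) and `band_spec`.
#' @export
parse_aberration <- function(token) {
  raw <- trimws(token)
  if (!nzchar(raw)) stop("empty aberration token")
  tok <- raw
  gain_prefix <- grepl("^\\+", tok)
  loss_prefix <- grepl("^[−-]", tok)
  if (gain_prefix || loss_prefix) tok <- sub("^[+−-]\\s*", "", tok)

  ab <- function(kind, primary = NA_character_, partners = character(),
                 band_spec = "", delta = 0L) {
    structure(list(raw = raw, kind = kind, gain_prefix = gain_prefix,
                   delta = delta, primary = primary, partners = partners,
                   band_spec = band_spec),
              class = "aberration")
  }

  # bare whole-chromosome gain/loss
  if (grepl("^([0-9]{1,2}|X|Y)$", tok)) {
    if (!(tok %in% CHROM_LABELS))
      stop("invalid chromosome label in token '", raw, "'")
    if (!gain_prefix && !loss_prefix)
      stop("bare chromosome token '", raw, "' needs a +/- prefix")
    return(ab("num", primary = tok, delta = if (gain_prefix) 1L else -1L))
  }

  m <- regmatches(tok, regexec(
    "^(del|dup|der|iso|add)\\(([0-9]{1,2}|X|Y)([pq]?)\\)(.*)$", tok))[[1]]
  if (length(m) == 0) {
    warning("unrecognised aberration token '", raw, "' kept as kind 'other'",
            call. = FALSE)
    return(ab("other"))
  }
  kind <- m[2]; primary <- m[3]; band <- m[4]; rest <- m[5]
  if (!(primary %in% CHROM_LABELS))
    stop("invalid chromosome label '", primary, "' in token '", raw, "'")

  partners <- character()
  if (kind == "der" && grepl("^t\\(", rest)) {
    tm <- regmatches(rest, regexec("^t\\(([0-9XY;]+)\\)(.*)$", rest))[[1]]
    if (length(tm) == 0)
      stop("malformed translocation in token '", raw, "'")
    partners <- strsplit(tm[2], ";", fixed = TRUE)[[1]]
    bad <- setdiff(partners, CHROM_LABELS)
    if (length(bad))
      stop("invalid chromosome label '", bad[1], "' in token '", raw, "'")
    rest <- tm[3]
  }
  if (nzchar(rest)) {
    bm <- regmatches(rest, regexec("^\\(([^()]*)\\)$", rest))[[1]]
    if (length(bm) == 0) {
      warning("unrecognised aberration token '", raw, "' kept as kind 'other'",
              call. = FALSE)
      return(ab("other"))
    }
    band <- paste0(band, bm[2])
  }
  ab(kind, primary = primary, partners = partners, band_spec = band)
}

#' @export
format.aberration <- function(x, ...) x$raw

#' @export
print.aberration <- function(x, ...) {
  cat(sprintf("<aberration> %s  [kind=%s primary=%s%s%s]\n", x$raw, x$kind,
              x$primary,
              if (length(x$partners)) paste0(" t:", paste(x$partners, collapse = ";")) else "",
              if (nzchar(x$band_spec)) paste0(" band:", x$band_spec) else ""))
  invisible(x)
}

split_toplevel <- function(text, sep = ",") {
  # split on `sep` outside parentheses
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; out <- character(); cur <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) {
      out <- c(out, paste(cur, collapse = "")); cur <- character()
    } else cur <- c(cur, ch)
  }
  c(out, paste(cur, collapse = ""))
}

#' Parse an ISCN-style karyotype string into a clone record
#'
#' The string starts with a modal chromosome count, optionally followed by an
#' observed count range in parentheses (`47 (44~49)`; `~`, en-dash and `-`
#' all accepted as the range separator), then the sex complement, then a
#' comma-separated aberration list.  A leading "and " before the final token
#' is tolerated.
#'
#' @param text Karyotype string, e.g. `"46,XX"` or
#'   `"47 (44~49), XX, del(2)(p21), der(3)t(3;5)"`.
#' @param n_metaphases,total_metaphases Optional clone bookkeeping: number of
#'   metaphases showing this clone out of the number examined.
#' @return Object of class `clone_karyotype` with fields `modal_count`,
#'   `count_range` (length-2 integer), `sex_complement`, `aberrations` (list
#'   of [parse_aberration()] results), `n_metaphases`, `total_metaphases`.
#' @examples
#' k <- parse_iscn("47 (44~49), XX, del(2)(p21), der(3)t(3;5)")
#' k$modal_count
#' @export
parse_iscn <- function(text, n_metaphases = NA_integer_,
                       total_metaphases = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  text0 <- sub("\\.\\s*$", "", trimws(text))
  fields <- trimws(split_toplevel(text0))
  fields <- fields[nzchar(fields)]
  if (length(fields) < 2L)
    stop("karyotype string needs at least a count and a sex complement: '",
         text0, "'")

  cm <- regmatches(fields[1], regexec(
    "^([0-9]+)\\s*(?:\\(\\s*([0-9]+)\\s*[~–−-]\\s*([0-9]+)\\s*\\))?$",
    fields[1]))[[1]]
  if (length(cm) == 0 || !nzchar(cm[2]))
    stop("malformed count prefix: '", fields[1], "'")
  modal <- as.integer(cm[2])
  rng <- if (nzchar(cm[3])) c(as.integer(cm[3]), as.integer(cm[4]))
         else c(modal, modal)
  if (!(rng[1] <= modal && modal <= rng[2]))
    stop("modal count ", modal, " outside its stated range (",
         rng[1], ", ", rng[2], ")")

  sex <- fields[2]
  if (!grepl("^[XY]{1,3}$", sex))
    stop("expected a sex complement (e.g. XX, XY, X), got '", sex, "'")

  tokens <- fields[-(1:2)]
  tokens <- sub("^and\\s+", "", tokens)
  aberrations <- lapply(tokens, parse_aberration)

  structure(list(modal_count = modal, count_range = rng,
                 sex_complement = sex, aberrations = aberrations,
                 n_metaphases = as.integer(n_metaphases),
                 total_metaphases = as.integer(total_metaphases)),
            class = "clone_karyotype")
}

#' Serialize a clone back to its ISCN string
#'
#' Round-trips: the emitted aberration tokens are the verbatim `raw` fields.
#' @param clone A `clone_karyotype`.
#' @return Character scalar.
#' @export
format_iscn <- function(clone) {
  stopifnot(inherits(clone, "clone_karyotype"))
  count <- if (clone$count_range[1] == clone$count_range[2])
    as.character(clone$modal_count)
  else sprintf("%d (%d~%d)", clone$modal_count, clone$count_range[1],
               clone$count_range[2])
  paste(c(count, clone$sex_complement,
          vapply(clone$aberrations, function(a) a$raw, character(1))),
        collapse = ", ")
}

#' @export
print.clone_karyotype <- function(x, ...) {
  cat("<clone_karyotype>", format_iscn(x), "\n")
  if (!is.na(x$n_metaphases))
    cat(sprintf("  clone in %d/%d metaphases\n", x$n_metaphases,
                x$total_metaphases))
  invisible(x)
}

new_metaphase <- function(id, chromosome_count, sex_complement, aberrations) {
  structure(list(id = id, chromosome_count = as.integer(chromosome_count),
                 sex_complement = sex_complement, aberrations = aberrations),
            class = "metaphase")
}

#' @export
print.metaphase <- function(x, ...) {
  cat(sprintf("<metaphase %s> count=%d, %s, %d aberrations\n", x$id,
              x$chromosome_count, x$sex_complement, length(x$aberrations)))
  invisible(x)
}

baseline_count <- function(sex_complement) 44L + nchar(sex_complement)

#' Reconstruct a metaphase set from a main clone plus recurrent extras
#'
#' Produces `n_metaphases` copies of the main clone; each extra aberration is
#' added to its stated number of metaphases, assigned to the lowest-index
#' metaphases first (a documented, deterministic rule); remaining metaphases
#' up to `total_metaphases` are normal-baseline.
#'
#' @param clone A `clone_karyotype` carrying `n_metaphases` and
#'   `total_metaphases` (or supply them here).
#' @param extras List of extra recurrent aberrations, each either an
#'   `aberration` / token string with a `recurrence` count:
#'   `list(list(token = "del(X)", recurrence = 2), ...)`.
#' @param n_metaphases,total_metaphases Override the clone's bookkeeping.
#' @return List of `metaphase` objects of length `total_metaphases`.
#' @export
expand_clone <- function(clone, extras = list(),
                         n_metaphases = clone$n_metaphases,
                         total_metaphases = clone$total_metaphases) {
  stopifnot(inherits(clone, "clone_karyotype"))
  n <- as.integer(n_metaphases); total <- as.integer(total_metaphases)
  if (is.na(n) || is.na(total))
    stop("clone needs n_metaphases and total_metaphases")
  if (n > total) stop("n_metaphases exceeds total_metaphases")

  base <- baseline_count(clone$sex_complement)
  mk <- function(i) {
    if (i <= n)
      new_metaphase(sprintf("m%02d", i), clone$modal_count,
                    clone$sex_complement, clone$aberrations)
    else
      new_metaphase(sprintf("m%02d", i), base, clone$sex_complement, list())
  }
  metas <- lapply(seq_len(total), mk)

  for (ex in extras) {
    abr <- if (inherits(ex$token, "aberration")) ex$token
           else parse_aberration(ex$token)
    r <- as.integer(ex$recurrence)
    if (r > total)
      stop("extra aberration '", abr$raw, "' recurrence ", r,
           " exceeds total metaphases ", total)
    dlt <- if (abr$kind == "num") abr$delta
           else if (abr$gain_prefix) 1L else 0L
    for (i in seq_len(r)) {
      metas[[i]]$aberrations <- c(metas[[i]]$aberrations, list(abr))
      metas[[i]]$chromosome_count <- metas[[i]]$chromosome_count + dlt
    }
  }
  metas
}

#' Per-chromosome centromere counts of a metaphase
#'
#' Starts from the baseline complement (two per autosome, sex chromosomes per
#' `baseline_sex`).  A gain-prefixed structural aberration adds one centromere
#' of its primary chromosome; a non-prefixed structural aberration replaces a
#' normal homolog (count unchanged); bare `+N`/`-N` tokens adjust whole
#' chromosomes.  Chromosomes absent from the baseline (Y with a female
#' baseline) have no centromere class and are omitted.
#'
#' @param m A `metaphase`.
#' @param baseline_sex Sex complement defining which sex-chromosome classes
#'   exist (default: the metaphase's own).  The metaphase's own sex
#'   complement supplies the observed sex-chromosome copy numbers, so
#'   "45,X" against an "XX" baseline shows one X centromere.
#' @return Named integer vector, chromosome label -> centromere count.
#' @export
centromere_counts <- function(m, baseline_sex = m$sex_complement) {
  stopifnot(inherits(m, "metaphase"))
  own <- strsplit(m$sex_complement, "")[[1]]
  base <- strsplit(baseline_sex, "")[[1]]
  sex_labels <- intersect(c("X", "Y"), union(own, base))
  labels <- c(as.character(1:22), sex_labels)
  counts <- stats::setNames(rep(2L, length(labels)), labels)
  for (s in sex_labels) counts[s] <- sum(own == s)

  for (a in m$aberrations) {
    if (a$kind == "other") next
    if (!(a$primary %in% names(counts)))
      stop("aberration '", a$raw, "' targets chromosome ", a$primary,
           " absent from the ", baseline_sex, " baseline")
    dlt <- if (a$kind == "num") a$delta else if (a$gain_prefix) 1L else 0L
    counts[a$primary] <- counts[a$primary] + dlt
    if (counts[a$primary] < 0L)
      stop("centromere count of chromosome ", a$primary,
           " dropped below zero in metaphase ", m$id)
  }
  counts
}

#' Internal-consistency check of a metaphase
#'
#' Compares the declared chromosome count with the sum of derived centromere
#' counts.  Published karyotypes are sometimes arithmetically inconsistent
#' (a stated modal count that the listed gains cannot produce); this check
#' reports such discrepancies rather than resolving them.
#'
#' @param m A `metaphase`.
#' @param baseline_sex Baseline sex complement.
#' @return List with `ok`, `declared`, `derived`, `discrepancy`.
#' @export
check_metaphase <- function(m, baseline_sex = m$sex_complement) {
  derived <- sum(centromere_counts(m, baseline_sex))
  list(ok = derived == m$chromosome_count, declared = m$chromosome_count,
       derived = derived, discrepancy = derived - m$chromosome_count)
}

#' Read a metaphase file (one ISCN string per line, `#` comments)
#'
#' Each line is parsed as one metaphase's karyotype.
#' @param path File path.
#' @return List of `metaphase` objects.
#' @export
read_metaphases <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    cl <- parse_iscn(lines[i])
    new_metaphase(sprintf("m%02d", i), cl$modal_count, cl$sex_complement,
                  cl$aberrations)
  })
}

#' Read a clone file (TSV: karyotype, n_metaphases, total_metaphases)
#' @param path File path.
#' @return List of `clone_karyotype` objects.
#' @export
read_clones <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("karyotype", "n_metaphases", "total_metaphases")
  if (!all(needed %in% names(df)))
    stop("clone file needs columns: ", paste(needed, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    parse_iscn(df$karyotype[i], df$n_metaphases[i], df$total_metaphases[i]))
}
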