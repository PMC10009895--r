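#' @title HLA allele nomenclature
#'
#' @description
#' HLA alleles are named `<locus>*<field1>:<field2>:...` with up to four
#' colon-separated numeric fields. The first three fields determine the
#' coding sequence (the "CDS level"); the fourth distinguishes variants in
#' non-coding regions. `parse_allele()` normalizes an allele string into an
#' `hla_allele` object; `format()` reproduces the canonical text.
#'
#' @name hla-alleles
NULL

# Loci participating in typing, matching and reference augmentation.
HLA_LOCI <- c("HLA-A", "HLA-B", "HLA-C", "HLA-DRA", "HLA-DRB1", "HLA-DRB3",
              "HLA-DRB4", "HLA-DRB5", "HLA-DQA1", "HLA-DQB1", "HLA-DPA1",
              "HLA-DPB1")

HLA_CLASS_I  <- c("HLA-A", "HLA-B", "HLA-C")
HLA_CLASS_II <- setdiff(HLA_LOCI, HLA_CLASS_I)

#' Parse an HLA allele string
#'
#' Accepts names with or without the `HLA-` prefix; internal whitespace
#' (including typographic spaces that creep in when allele names are
#' typeset, e.g. `"HLA-B*35: 08:01"`) is stripped. The locus is stored
#' canonically with the `HLA-` prefix.
#'
#' @param text Allele string, e.g. `"HLA-A*24:02:01:01"` or `"DRB1*13"`.
#' @return An `hla_allele`: list with `gene` (canonical locus name),
#'   `fields` (character vector of 1-4 numeric fields, leading zeros
#'   preserved) and `raw` (the input text).
#' @examples
#' a <- parse_allele("HLA-A*24:02:01:01")
#' format(a)
#' allele_resolution(a)
#' @export
parse_allele <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  s <- gsub("[\\s ]+", "", text, perl = TRUE)
  parts <- strsplit(s, "*", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !nzchar(parts[2L]))
    stop("cannot parse allele '", raw, "': expected '<locus>*<fields>'",
         call. = FALSE)
  gene <- toupper(parts[1L])
  if (!startsWith(gene, "HLA-")) gene <- paste0("HLA-", gene)
  if (!gene %in% HLA_LOCI)
    stop("unsupported HLA locus '", gene, "' in allele '", raw, "'",
         call. = FALSE)
  fields <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
  if (length(fields) < 1L || length(fields) > 4L)
    stop("allele '", raw, "' has ", length(fields),
         " fields; expected 1-4", call. = FALSE)
  if (!all(grepl("^[0-9]+$", fields)))
    stop("allele '", raw, "' has a non-numeric field", call. = FALSE)
  structure(list(gene = gene, fields = fields, raw = raw),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$gene, "*", paste(x$fields, collapse = ":"))
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele>", format(x), "\n")
  invisible(x)
}

#' Resolution (number of fields) of an allele
#' @param a An `hla_allele`.
#' @return Integer in 1..4.
#' @export
allele_resolution <- function(a) {
  stopifnot(inherits(a, "hla_allele"))
  length(a$fields)
}

#' Truncate an allele to a coarser resolution
#'
#' Truncation to three fields gives the CDS-level name; truncation to the
#' current resolution is the identity. Truncating beyond the available
#' fields is an error - fields are never silently padded.
#'
#' @param a An `hla_allele`.
#' @param n Target number of fields, `1 <= n <= allele_resolution(a)`.
#' @return An `hla_allele` with the first `n` fields.
#' @examples
#' truncate_allele(parse_allele("HLA-DRB3*01:01:02:02"), 3)
#' @export
truncate_allele <- function(a, n) {
  stopifnot(inherits(a, "hla_allele"))
  n <- as.integer(n)
  if (n < 1L) stop("resolution must be >= 1", call. = FALSE)
  if (n > allele_resolution(a))
    stop("cannot truncate ", format(a), " to ", n, " fields: only ",
         allele_resolution(a), " available", call. = FALSE)
  structure(list(gene = a$gene, fields = a$fields[seq_len(n)],
                 raw = a$raw),
            class = "hla_allele")
}

#' CDS-level name of an allele
#'
#' The first (up to) three fields, which determine the coding sequence.
#'
#' @param a An `hla_allele`.
#' @return Canonical allele string at CDS resolution.
#' @export
cds_name <- function(a) {
  format(truncate_allele(a, min(3L, allele_resolution(a))))
}

#' Compare two alleles at a given resolution
#'
#' In strict mode (the default) a comparison at `n` fields requires both
#' alleles to carry at least `n` fields; otherwise the first
#' `min(n, res(a), res(b))` fields are compared. Alleles of different loci
#' never match.
#'
#' @param a,b `hla_allele` objects.
#' @param n Number of fields to compare.
#' @param strict Require both alleles to have at least `n` fields.
#' @return `TRUE` or `FALSE`.
#' @examples
#' alleles_match_at(parse_allele("A*24:02:01:01"),
#'                  parse_allele("A*24:02:01"), 3)
#' @export
alleles_match_at <- function(a, b, n, strict = TRUE) {
  stopifnot(inherits(a, "hla_allele"), inherits(b, "hla_allele"), n >= 1)
  if (!identical(a$gene, b$gene)) return(FALSE)
  if (strict && (allele_resolution(a) < n || allele_resolution(b) < n))
    return(FALSE)
  m <- min(n, allele_resolution(a), allele_resolution(b))
  identical(a$fields[seq_len(m)], b$fields[seq_len(m)])
}

#' Construct a subject typing
#'
#' @param subject_id Subject identifier.
#' @param alleles Named list, locus name -> list of 0-2 `hla_allele`.
#'   Loci absent from the list are untyped; an empty list records a locus
#'   known to carry no allele (e.g. haplotypes without an HLA-DRB3 gene).
#' @return An `hla_typing` object.
#' @export
hla_typing <- function(subject_id, alleles = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(alleles))
  if (length(alleles)) {
    if (is.null(names(alleles)) || !all(names(alleles) %in% HLA_LOCI))
      stop("typing loci must be named and drawn from the supported set",
           call. = FALSE)
    for (loc in names(alleles)) {
      al <- alleles[[loc]]
      if (length(al) > 2L)
        stop("more than 2 alleles at ", loc, " for subject ", subject_id,
             call. = FALSE)
      for (a in al) {
        stopifnot(inherits(a, "hla_allele"))
        if (!identical(a$gene, loc))
          stop("allele ", format(a), " filed under locus ", loc,
               call. = FALSE)
      }
    }
  }
  structure(list(subject_id = subject_id, alleles = alleles),
            class = "hla_typing")
}

#' @export
print.hla_typing <- function(x, ...) {
  cat("<hla_typing>", x$subject_id, "\n")
  for (loc in names(x$alleles)) {
    al <- x$alleles[[loc]]
    cat("  ", loc, ": ",
        if (length(al)) paste(vapply(al, format, ""), collapse = ", ")
        else "-", "\n", sep = "")
  }
  invisible(x)
}

#' Load a typing table
#'
#' Reads a CSV with columns `subject_id`, `locus`, `allele` (one row per
#' allele; the allele may be written with or without its locus prefix).
#' Loci without rows for a subject are untyped; a locus can be recorded as
#' explicitly empty with allele `"-"`.
#'
#' @param path CSV file path.
#' @return List of `hla_typing`, one per subject, in order of first
#'   appearance.
#' @export
load_typing_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "locus", "allele")
  if (!all(need %in% names(df)))
    stop("typing table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    sid <- df$subject_id[i]
    loc <- df$locus[i]
    if (!startsWith(toupper(loc), "HLA-")) loc <- paste0("HLA-", toupper(loc))
    if (!loc %in% HLA_LOCI)
      stop("row ", i, ": unsupported locus '", df$locus[i], "'",
           call. = FALSE)
    if (is.null(out[[sid]])) out[[sid]] <- list()
    if (is.null(out[[sid]][[loc]])) out[[sid]][[loc]] <- list()
    txt <- trimws(df$allele[i])
    if (identical(txt, "-") || !nzchar(txt)) next  # explicit empty locus
    a <- tryCatch(
      if (grepl("*", txt, fixed = TRUE)) parse_allele(txt)
      else parse_allele(paste0(loc, "*", txt)),
      error = function(e)
        stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
    if (!identical(a$gene, loc))
      stop("row ", i, ": allele ", format(a), " does not belong to locus ",
           loc, call. = FALSE)
    if (length(out[[sid]][[loc]]) >= 2L)
      stop("row ", i, ": more than 2 alleles at ", loc, " for subject ",
           sid, call. = FALSE)
    out[[sid]][[loc]] <- c(out[[sid]][[loc]], list(a))
  }
  lapply(names(out), function(sid) hla_typing(sid, out[[sid]]))
}

#' Packaged SV-BR-1-GM cohort typings
#'
#' Typings for the SV-BR-1-GM cell line and the four trial subjects (A001,
#' A002, A003, B001), transcribed from the published typing table.
#'
#' @return Named list of `hla_typing` (first element is the cell line).
#' @export
load_packaged_typings <- function() {
  path <- system.file("extdata", "sv_br_1_gm_typings.csv",
                      package = "allovax", mustWork = TRUE)
  t <- load_typing_table(path)
  names(t) <- vapply(t, function(x) x$subject_id, "")
  t
}
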