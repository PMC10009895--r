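#' Expression gate from a vehicle/IFN-gamma call table
#'
#' HLA matching credits a cell-line allele only if it is expressed at
#' least following IFN-gamma stimulation, so the gate is the OR of the
#' vehicle and IFN-gamma expression calls. Names are canonicalized to the
#' CDS-level allele string.
#'
#' @param calls `data.frame` with columns `allele`, `expressed_vehicle`,
#'   `expressed_ifng` (as written by [expression_call_table()] or loaded
#'   with [load_expression_table()]).
#' @return Named logical vector, one entry per allele at CDS resolution.
#' @export
expression_gate <- function(calls) {
  need <- c("allele", "expressed_vehicle", "expressed_ifng")
  stopifnot(all(need %in% names(calls)))
  nm <- vapply(calls$allele, function(s) cds_name(parse_allele(s)), "")
  setNames(as.logical(calls$expressed_vehicle) |
           as.logical(calls$expressed_ifng), nm)
}

#' Load an allele expression-call table
#'
#' TSV with columns `allele`, `expressed_vehicle`, `expressed_ifng`.
#'
#' @param path TSV path.
#' @return `data.frame` of calls.
#' @export
load_expression_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged SV-BR-1-GM allele expression calls
#'
#' Expression calls for the cell line's typed alleles under vehicle and
#' IFN-gamma conditions, transcribed from the published allele-level
#' RNA-seq expression figures (1-TPM threshold).
#'
#' @return `data.frame` with `allele`, `expressed_vehicle`,
#'   `expressed_ifng`.
#' @export
load_packaged_expression_calls <- function() {
  load_expression_table(system.file("extdata",
                                    "sv_br_1_gm_expression_calls.tsv",
                                    package = "allovax", mustWork = TRUE))
}

# deduplicate alleles within a locus by canonical full-resolution string
# (homozygous entries count once as match candidates)
.unique_alleles <- function(alleles) {
  if (!length(alleles)) return(list())
  keys <- vapply(alleles, format, "")
  alleles[!duplicated(keys)]
}

.gate_of <- function(line_allele, gate) {
  key <- cds_name(line_allele)
  if (!key %in% names(gate))
    stop("expression gate has no entry for line allele ", key,
         call. = FALSE)
  gate[[key]]
}

#' Match one locus between a patient and the cell line
#'
#' Allele-level matching compares the first three fields (the CDS level)
#' and requires the line allele to pass the expression gate. If no pair
#' matches at allele level, group matching is attempted at 2 fields, then
#' 1 field, reporting the finest resolution at which any pair matches
#' (gated as well, unless `gate_group = FALSE`). Line alleles that match
#' by sequence but fail the gate are collected in `expression_gated_out`.
#' Group matches among pairs not already matched at allele level are
#' always recorded in `group_matches`, since a locus can carry both an
#' allele-level and an additional group-level correspondence.
#'
#' @param patient List of `hla_allele` for the patient at this locus
#'   (0-2; homozygous duplicates count once).
#' @param line List of `hla_allele` for the cell line at this locus.
#' @param gate Named logical vector from [expression_gate()].
#' @param locus Locus name (checked against the alleles).
#' @param gate_group Apply the expression gate to group matches too
#'   (default `TRUE`).
#' @return A `match_result`: list with `locus`, `level` (`"allele"`,
#'   `"group"` or `"none"`), `matched_alleles` (list of
#'   `(patient, line)` pairs), `group_resolution`, `group_matches`,
#'   `expression_gated_out` and `untyped`.
#' @export
match_locus <- function(patient, line, gate, locus = NULL,
                        gate_group = TRUE) {
  all_alleles <- c(patient, line)
  if (is.null(locus)) {
    if (!length(all_alleles))
      stop("locus must be given when both allele lists are empty",
           call. = FALSE)
    locus <- all_alleles[[1L]]$gene
  }
  for (a in all_alleles)
    if (!identical(a$gene, locus))
      stop("allele ", format(a), " does not belong to locus ", locus,
           call. = FALSE)
  res <- list(locus = locus, level = "none", matched_alleles = list(),
              group_resolution = NA_integer_, group_matches = list(),
              expression_gated_out = list(),
              untyped = !length(patient) || !length(line))
  class(res) <- "match_result"
  patient <- .unique_alleles(patient)
  line <- .unique_alleles(line)
  if (!length(patient) || !length(line)) return(res)

  allele_pairs <- list()
  gated_out <- list()
  matched_line <- character()
  for (p in patient) for (q in line) {
    if (alleles_match_at(p, q, 3L, strict = TRUE)) {
      if (.gate_of(q, gate)) {
        allele_pairs <- c(allele_pairs, list(list(patient = p, line = q)))
        matched_line <- c(matched_line, format(q))
      } else {
        gated_out <- c(gated_out, list(q))
      }
    }
  }
  # group matches among pairs not matched at allele level, finest first
  group_pairs <- list()
  group_res <- NA_integer_
  for (nres in c(2L, 1L)) {
    for (p in patient) for (q in line) {
      already <- any(vapply(allele_pairs, function(pr)
        identical(format(pr$patient), format(p)) &&
        identical(format(pr$line), format(q)), TRUE))
      if (already) next
      if (alleles_match_at(p, q, nres, strict = TRUE) &&
          !alleles_match_at(p, q, min(3L, nres + 1L), strict = TRUE)) {
        ok <- !gate_group || .gate_of(q, gate)
        if (!ok) {
          gated_out <- c(gated_out, list(q))
          next
        }
        group_pairs <- c(group_pairs,
                         list(list(patient = p, line = q,
                                   resolution = nres)))
        if (is.na(group_res)) group_res <- nres
      }
    }
    if (length(group_pairs)) break
  }
  res$matched_alleles <- allele_pairs
  res$group_matches <- group_pairs
  res$expression_gated_out <- .unique_alleles(gated_out)
  if (length(allele_pairs)) {
    res$level <- "allele"
    res$group_resolution <- group_res
  } else if (length(group_pairs)) {
    res$level <- "group"
    res$group_resolution <- group_res
  }
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>", x$locus, "level =", x$level)
  if (length(x$matched_alleles))
    cat(" [", paste(vapply(x$matched_alleles,
                           function(p) cds_name(p$line), ""),
                    collapse = ", "), "]")
  if (length(x$group_matches))
    cat(" group:",
        paste(vapply(x$group_matches, function(p)
          format(truncate_allele(p$patient, p$resolution)), ""),
          collapse = ", "))
  if (length(x$expression_gated_out))
    cat(" gated-out:",
        paste(vapply(x$expression_gated_out, cds_name, ""),
              collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Match a whole subject typing against the cell line
#'
#' Loci typed on only one side (e.g. alpha-chain loci not typed in the
#' patients) yield `level = "none"` flagged `untyped` rather than an
#' error.
#'
#' @param patient,line `hla_typing` objects.
#' @param gate Named logical vector from [expression_gate()].
#' @param gate_group Apply the gate to group matches (default `TRUE`).
#' @return A `match_report`: per-locus `match_result` plus Class I / II
#'   rollups of allele-level matched loci.
#' @export
match_subject <- function(patient, line, gate, gate_group = TRUE) {
  stopifnot(inherits(patient, "hla_typing"), inherits(line, "hla_typing"))
  loci <- union(names(line$alleles), names(patient$alleles))
  loci <- HLA_LOCI[HLA_LOCI %in% loci]
  per_locus <- lapply(loci, function(loc) {
    match_locus(patient$alleles[[loc]] %||% list(),
                line$alleles[[loc]] %||% list(),
                gate, locus = loc, gate_group = gate_group)
  })
  names(per_locus) <- loci
  allele_loci <- loci[vapply(per_locus, function(r)
    r$level == "allele", TRUE)]
  structure(list(subject_id = patient$subject_id, loci = per_locus,
                 class_I_loci_matched =
                   intersect(allele_loci, HLA_CLASS_I),
                 class_II_loci_matched =
                   intersect(allele_loci, HLA_CLASS_II)),
            class = "match_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>", x$subject_id, "\n")
  for (r in x$loci) print(r)
  cat("  Class I allele-level:",
      paste(x$class_I_loci_matched, collapse = ", "), "\n")
  cat("  Class II allele-level:",
      paste(x$class_II_loci_matched, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort-wide match table
#'
#' One row per subject and locus, with the match level, the CDS-level
#' names of allele-matched line alleles, group matches at the resolution
#' found, and gated-out sequence matches.
#'
#' @param typings List of `hla_typing` (the patients).
#' @param line `hla_typing` of the cell line.
#' @param gate Named logical from [expression_gate()].
#' @param gate_group Apply the gate to group matches (default `TRUE`).
#' @return `data.frame` with columns `subject_id`, `locus`, `level`,
#'   `allele_matches`, `group_resolution`, `group_matches`, `gated_out`.
#' @export
cohort_match_table <- function(typings, line, gate, gate_group = TRUE) {
  stopifnot(length(typings) >= 1L)
  sids <- vapply(typings, function(t) t$subject_id, "")
  if (anyDuplicated(sids))
    stop("duplicate subject ids in cohort", call. = FALSE)
  rows <- list()
  for (t in typings) {
    rep <- match_subject(t, line, gate, gate_group = gate_group)
    for (loc in names(rep$loci)) {
      r <- rep$loci[[loc]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = t$subject_id, locus = loc, level = r$level,
        allele_matches = paste(vapply(r$matched_alleles,
                                      function(p) cds_name(p$line), ""),
                               collapse = ";"),
        group_resolution = r$group_resolution,
        group_matches = paste(vapply(r$group_matches, function(p)
          format(truncate_allele(p$patient, p$resolution)), ""),
          collapse = ";"),
        gated_out = paste(vapply(r$expression_gated_out, cds_name, ""),
                          collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @importFrom utils read.delim
NULL
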