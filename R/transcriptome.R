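#' Construct a set of transcript records
#'
#' A transcriptome is held as a data frame with columns `id`, `sequence`
#' and `source` (`"reference"` or `"hla_allele"`). Sequences are
#' upper-case over the alphabet A/C/G/T/N; ids must be unique.
#'
#' @param id Character vector of transcript ids.
#' @param sequence Character vector of nucleotide sequences.
#' @param source `"reference"` or `"hla_allele"`, recycled.
#' @return A `data.frame` of transcript records.
#' @export
transcript_records <- function(id, sequence, source = "reference") {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence for '", id[which(bad)[1L]],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate transcript id '", id[duplicated(id)][1L], "'",
         call. = FALSE)
  source <- rep_len(source, length(id))
  stopifnot(all(source %in% c("reference", "hla_allele")))
  data.frame(id = as.character(id), sequence = sequence, source = source,
             stringsAsFactors = FALSE)
}

#' Plan an augmentation of a reference transcriptome
#'
#' Describes the replacement of reference HLA transcripts by the typed
#' alleles of a cell line: transcripts on the removal list are dropped and
#' the allele sequences are appended.
#'
#' @param removal_ids Transcript ids to remove (unique).
#' @param insertions Transcript records (source `"hla_allele"`) to append.
#' @param sequence_kind `"CDS"` or `"CDS_plus_UTR"`; records whether the
#'   inserted allele sequences carry untranslated regions.
#' @return An `augmentation_plan` object.
#' @export
augmentation_plan <- function(removal_ids = character(),
                              insertions = transcript_records(character(),
                                                              character()),
                              sequence_kind = c("CDS", "CDS_plus_UTR")) {
  sequence_kind <- match.arg(sequence_kind)
  removal_ids <- as.character(removal_ids)
  if (anyDuplicated(removal_ids))
    stop("removal_ids contains duplicates", call. = FALSE)
  if (nrow(insertions) && anyDuplicated(insertions$id))
    stop("duplicate insertion id", call. = FALSE)
  structure(list(removal_ids = removal_ids, insertions = insertions,
                 sequence_kind = sequence_kind),
            class = "augmentation_plan")
}

#' Build a line-specific augmented transcriptome
#'
#' Removes the planned reference transcripts (typically all HLA transcripts
#' absent from the cell line, which would otherwise absorb reads from the
#' highly similar alleles actually present) and appends the typed allele
#' sequences. Surviving reference order is preserved; insertions follow.
#'
#' @param reference Transcript records (see [transcript_records()]).
#' @param plan An [augmentation_plan()].
#' @return Transcript records of the augmented transcriptome.
#' @export
build_augmented_transcriptome <- function(reference, plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  missing_ids <- setdiff(plan$removal_ids, reference$id)
  if (length(missing_ids))
    stop("removal id(s) not found in reference: ",
         paste(missing_ids, collapse = ", "),
         " (stale removal list?)", call. = FALSE)
  surviving <- reference[!reference$id %in% plan$removal_ids, ,
                         drop = FALSE]
  ins <- plan$insertions
  if (nrow(ins)) {
    if (any(!nzchar(ins$sequence)))
      stop("insertion with empty sequence", call. = FALSE)
    clash <- intersect(ins$id, surviving$id)
    if (length(clash))
      stop("insertion id(s) already present in reference: ",
           paste(clash, collapse = ", "), call. = FALSE)
    ins$source <- "hla_allele"
  }
  out <- rbind(surviving, ins)
  rownames(out) <- NULL
  out
}

#' Read a transcriptome from FASTA
#'
#' The id is the header token before the first whitespace.
#'
#' @param path FASTA file.
#' @param source Source label for the records.
#' @return Transcript records.
#' @export
read_transcripts_fasta <- function(path, source = "reference") {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  transcript_records(ids, as.character(x), source = source)
}

#' Write transcript records to FASTA
#'
#' @param records Transcript records.
#' @param path Output file; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read short reads from FASTA or FASTQ
#'
#' Quality scores are ignored; only the sequences enter pseudoalignment.
#'
#' @param path Read file; format is inferred from the extension
#'   (`.fastq`/`.fq` vs anything else) unless given.
#' @param format `"fasta"` or `"fastq"`.
#' @return Character vector of read sequences, named by read id.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
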