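#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. Defaults
#' emulate the study conditions: 150-base reads, 21-mer index, allele
#' pairs at 92% identity (the published DRB1/DRB3 cross-similarity range
#' is 91-93%), and seven grade-labelled studies with 40 samples per grade
#' group, 30 planted genes at |log2 FC| = 2 and residual SD 0.5.
#'
#' @param read_length Read length in bases.
#' @param n_reads Number of simulated reads.
#' @param error_rate Per-base substitution probability, `[0, 0.1)`.
#' @param k k-mer length.
#' @param allele_identity Target pairwise identity of an allele pair,
#'   `[0.80, 1.0]`.
#' @param allele_length Allele CDS length in bases.
#' @param utr_length Length of each (5' and 3') untranslated region used
#'   when full transcripts are simulated.
#' @param study List of meta-analysis simulation parameters: `n_studies`,
#'   `n_genes`, `samples_per_group`, `n_planted`, `planted_lfc` (log2),
#'   `noise_sd`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(read_length = 150L, n_reads = 200000L,
                       error_rate = 0.001, k = 21L,
                       allele_identity = 0.92, allele_length = 800L,
                       utr_length = 150L,
                       study = list(n_studies = 7L, n_genes = 2000L,
                                    samples_per_group = 40L,
                                    n_planted = 30L, planted_lfc = 2,
                                    noise_sd = 0.5)) {
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)", call. = FALSE)
  if (allele_identity < 0.80 || allele_identity > 1.0)
    stop("allele_identity must be in [0.80, 1.0]", call. = FALSE)
  structure(list(read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 k = as.integer(k), allele_identity = allele_identity,
                 allele_length = as.integer(allele_length),
                 utr_length = as.integer(utr_length), study = study),
            class = "sim_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_positions <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a pair of homologous allele-like sequences
#'
#' A random coding-like sequence and a mutated copy whose Hamming
#' identity hits the target within one percentage point, with
#' substitutions uniformly placed - emulating the high (91-93%) identity
#' of paired HLA-DRB alleles.
#'
#' @param length Sequence length, >= 200 bases.
#' @param identity Target identity in `[0.80, 1.0]`.
#' @param ids Two transcript ids for the pair.
#' @param seed Optional RNG seed for reproducibility.
#' @return Transcript records (2 rows, source `"hla_allele"`).
#' @export
make_allele_pair <- function(length, identity,
                             ids = c("alleleA", "alleleB"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length >= 200L, length(ids) == 2L)
  if (identity < 0.80 || identity > 1.0)
    stop("identity must be in [0.80, 1.0]", call. = FALSE)
  a <- .random_seq(length)
  n_sub <- round((1 - identity) * length)
  b <- if (n_sub > 0)
    .mutate_positions(a, sample.int(length, n_sub)) else a
  transcript_records(ids, c(a, b), source = "hla_allele")
}

#' Generate a synthetic reference transcriptome with decoy HLA transcripts
#'
#' Produces mutually dissimilar random background transcripts, the
#' requested number of homologous allele pairs, and one "reference HLA"
#' decoy per pair (a diverged relative of the pair, mimicking reference
#' transcripts of alleles the cell line does not carry). The decoys are
#' part of the reference and listed for removal, so that an
#' [augmentation_plan()] can swap them for the line's alleles.
#'
#' @param n_background Number of background transcripts (>= 1).
#' @param allele_pairs Number of allele pairs.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @param bg_length_range Background transcript length range.
#' @return List with `reference` (records incl. decoys), `alleles`
#'   (records), `removal_ids` (the decoy ids).
#' @export
make_transcriptome <- function(n_background, allele_pairs = 0L,
                               config = sim_config(), seed = NULL,
                               bg_length_range = c(600L, 1500L)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_background >= 1L)
  bg_len <- sample(seq(bg_length_range[1L], bg_length_range[2L]),
                   n_background, replace = TRUE)
  bg <- transcript_records(sprintf("BG%03d", seq_len(n_background)),
                           vapply(bg_len, .random_seq, ""))
  alleles <- NULL
  decoys <- NULL
  if (allele_pairs > 0L) {
    for (i in seq_len(allele_pairs)) {
      pr <- make_allele_pair(config$allele_length, config$allele_identity,
                             ids = sprintf("HLA_SYN%d*%s", i,
                                           c("01:01:01", "02:01:01")))
      alleles <- rbind(alleles, pr)
      # a diverged relative the line does not carry; in the reference,
      # slated for removal
      n_sub <- round(0.12 * config$allele_length)
      decoy_seq <- .mutate_positions(pr$sequence[1L],
                                     sample.int(config$allele_length,
                                                n_sub))
      decoys <- rbind(decoys,
                      transcript_records(sprintf("HLA_DECOY%d", i),
                                         decoy_seq))
    }
  }
  reference <- rbind(bg, decoys)
  list(reference = reference,
       alleles = alleles %||%
         transcript_records(character(), character(),
                            source = "hla_allele"),
       removal_ids = if (is.null(decoys)) character() else decoys$id)
}

#' Simulate short reads from known abundances
#'
#' Transcripts are chosen with probability proportional to
#' `TPM x effective length` (so that TPM recomputed from the reads
#' matches the truth in expectation); start positions are uniform over
#' the valid positions; substitution errors are applied per base.
#' Transcripts shorter than the read length contribute whole-transcript
#' reads (clamped).
#'
#' @param transcripts Transcript records.
#' @param true_tpm Named numeric of true TPM per transcript id, summing
#'   to 1e6.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (`data.frame` with `id`, `true_tpm`, `true_counts`).
#' @export
simulate_reads <- function(transcripts, true_tpm, config = sim_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(setequal(names(true_tpm), transcripts$id))
  if (abs(sum(true_tpm) - 1e6) > 1e-3)
    stop("true_tpm must sum to 1e6", call. = FALSE)
  tpm <- true_tpm[transcripts$id]
  len <- nchar(transcripts$sequence)
  rl <- config$read_length
  eff <- pmax(1L, len - rl + 1L)
  prob <- tpm * eff
  counts <- as.vector(rmultinom(1L, config$n_reads, prob))
  tx_of_read <- rep.int(seq_len(nrow(transcripts)), counts)
  starts <- floor(runif(length(tx_of_read)) * eff[tx_of_read]) + 1L
  ends <- pmin(starts + rl - 1L, len[tx_of_read])
  reads <- substring(transcripts$sequence[tx_of_read], starts, ends)
  if (config$error_rate > 0 && length(reads)) {
    n_err <- rbinom(length(reads), nchar(reads), config$error_rate)
    hit <- which(n_err > 0L)
    for (i in hit) {
      reads[i] <- .mutate_positions(reads[i],
                                    sample.int(nchar(reads[i]), n_err[i]))
    }
  }
  names(reads) <- sprintf("read%06d", seq_along(reads))
  list(reads = reads,
       truth = data.frame(id = transcripts$id, true_tpm = as.numeric(tpm),
                          true_counts = counts,
                          stringsAsFactors = FALSE))
}

#' Simulate grade-labelled expression studies
#'
#' Each study draws independent per-gene baselines and Gaussian noise;
#' the planted genes (shared across studies) are shifted in grade-3
#' samples by the planted log2 fold change, alternating up/down.
#'
#' @param config A [sim_config()]; the `study` element supplies the
#'   parameters.
#' @param seed Optional RNG seed.
#' @param planted_lfc Override for the planted log2 fold change (0 gives
#'   null studies).
#' @return List with `studies` (list of [study_matrix()]) and `truth`
#'   (`data.frame` with `gene`, `direction`, `log2_fc`).
#' @export
simulate_grade_studies <- function(config = sim_config(), seed = NULL,
                                   planted_lfc = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$study
  if (!is.null(planted_lfc)) p$planted_lfc <- planted_lfc
  stopifnot(p$n_planted <= p$n_genes)
  genes <- sprintf("G%04d", seq_len(p$n_genes))
  planted <- genes[seq_len(p$n_planted)]
  dir_sign <- rep_len(c(1, -1), p$n_planted)
  shift <- setNames(rep(0, p$n_genes), genes)
  shift[planted] <- dir_sign * p$planted_lfc
  n3 <- p$samples_per_group
  n12 <- p$samples_per_group
  studies <- lapply(seq_len(p$n_studies), function(s) {
    baseline <- rnorm(p$n_genes, mean = 8, sd = 1.5)
    grade <- c(sample(1:2, n12, replace = TRUE), rep(3L, n3))
    m <- matrix(baseline, nrow = p$n_genes, ncol = n12 + n3) +
      outer(shift, as.numeric(grade == 3L)) +
      matrix(rnorm(p$n_genes * (n12 + n3), sd = p$noise_sd),
             nrow = p$n_genes)
    rownames(m) <- genes
    colnames(m) <- sprintf("S%d_%02d", s, seq_len(n12 + n3))
    study_matrix(sprintf("study%d", s), m, grade)
  })
  truth <- data.frame(gene = planted,
                      direction = ifelse(dir_sign > 0, "up", "down"),
                      log2_fc = dir_sign * p$planted_lfc,
                      stringsAsFactors = FALSE)
  list(studies = studies,
       truth = if (p$planted_lfc == 0) truth[0, , drop = FALSE] else truth)
}

# fillers for generated typings: first fields no real locus uses here
.FILLER_FIELDS <- sprintf("%02d", 71:98)

.fresh_field <- function(avoid) {
  pool <- setdiff(.FILLER_FIELDS, avoid)
  if (!length(pool)) stop("filler field pool exhausted", call. = FALSE)
  pool[1L]
}

#' Generate cohort typings with a prescribed match structure
#'
#' Builds one typing per subject so that each locus achieves exactly the
#' requested match level (and, for group matches, resolution) against the
#' cell line, assuming all line alleles pass the expression gate.
#'
#' @param n_subjects Number of subjects.
#' @param line `hla_typing` of the cell line.
#' @param match_spec List (length `n_subjects`, recycled if length 1) of
#'   named per-locus specs: `"allele"`, `"group"`, `"none"`, or
#'   `list(level = "group", resolution = 1 or 2)`. Loci of the line not
#'   mentioned get `"none"`.
#' @param seed Optional RNG seed.
#' @return List of `hla_typing`.
#' @export
make_cohort_typings <- function(n_subjects, line, match_spec,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(line, "hla_typing"), n_subjects >= 1L)
  if (length(match_spec) == 1L && n_subjects > 1L)
    match_spec <- rep(match_spec, n_subjects)
  stopifnot(length(match_spec) == n_subjects)
  all_true_gate <- local({
    keys <- unlist(lapply(line$alleles, function(al)
      vapply(al, cds_name, "")))
    setNames(rep(TRUE, length(keys)), keys)
  })
  make_none <- function(locus, avoid_first) {
    parse_allele(paste0(locus, "*", .fresh_field(avoid_first),
                        ":01:01"))
  }
  lapply(seq_len(n_subjects), function(i) {
    spec <- match_spec[[i]]
    alleles <- list()
    for (locus in union(names(line$alleles), names(spec))) {
      want <- spec[[locus]] %||% "none"
      if (is.character(want)) want <- list(level = want)
      level <- want$level
      line_al <- line$alleles[[locus]] %||% list()
      line_first <- vapply(line_al, function(a) a$fields[1L], "")
      if (level != "none" && !length(line_al))
        stop("cannot request a ", level, " match at untyped line locus ",
             locus, call. = FALSE)
      generated <- switch(
        level,
        allele = {
          base <- line_al[[1L]]
          list(truncate_allele(base, min(3L, allele_resolution(base))),
               make_none(locus, line_first))
        },
        group = {
          r <- want$resolution %||% 2L
          base <- line_al[[1L]]
          if (allele_resolution(base) < r)
            stop("line allele at ", locus,
                 " too coarse for a resolution-", r, " group match",
                 call. = FALSE)
          f <- base$fields[seq_len(r)]
          avoid <- unlist(lapply(line_al, function(a)
            if (allele_resolution(a) > r &&
                identical(a$fields[seq_len(r)], f))
              a$fields[r + 1L] else character()))
          f <- c(f, .fresh_field(avoid), rep("01", max(0L, 2L - r)))
          list(parse_allele(paste0(locus, "*",
                                   paste(f[seq_len(3L)],
                                         collapse = ":"))),
               make_none(locus, line_first))
        },
        none = list(make_none(locus, line_first),
                    make_none(locus, c(line_first, .FILLER_FIELDS[1L]))),
        stop("unknown match level '", level, "'", call. = FALSE))
      # verify the construction delivers exactly what was requested
      chk <- match_locus(generated, line_al, all_true_gate,
                         locus = locus)
      if (!identical(chk$level, level))
        stop("internal error: generated typing achieves level '",
             chk$level, "' instead of '", level, "' at ", locus,
             call. = FALSE)
      if (level == "group" && !is.null(want$resolution) &&
          !identical(chk$group_resolution, as.integer(want$resolution)))
        stop("internal error: generated group match at resolution ",
             chk$group_resolution, " instead of ", want$resolution,
             " at ", locus, call. = FALSE)
      alleles[[locus]] <- generated
    }
    hla_typing(sprintf("SYN%03d", i), alleles)
  })
}
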