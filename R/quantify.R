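#' Build a k-mer pseudoalignment index
#'
#' Every length-`k` substring of every transcript is recorded under its
#' canonical form (the lexicographically smaller of the forward and
#' reverse-complement 2-bit encodings) together with the set of transcripts
#' containing it. The effective length of a transcript is the number of
#' valid read start positions, floored at 1 so that transcripts shorter
#' than a read are retained rather than dropped.
#'
#' @param transcripts Transcript records (see [transcript_records()]).
#' @param k Odd k-mer length, 11-31. Default 21, suited to desk-scale
#'   synthetic transcriptomes.
#' @param read_length Read length in bases used for effective lengths.
#' @return A `kmer_index` object.
#' @export
build_index <- function(transcripts, k = 21L, read_length = 150L) {
  k <- as.integer(k)
  if (k < 11L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and between 11 and 31", call. = FALSE)
  stopifnot(nrow(transcripts) >= 1L)
  ptr <- .kmer_index_build(transcripts$id, transcripts$sequence, k)
  lengths <- nchar(transcripts$sequence)
  structure(list(ptr = ptr, k = k, read_length = as.integer(read_length),
                 ids = transcripts$id,
                 lengths = setNames(lengths, transcripts$id),
                 eff_lengths = setNames(pmax(1L, lengths - read_length + 1L),
                                        transcripts$id)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "|", length(x$ids), "transcripts |",
      format(.kmer_index_n_kmers(x$ptr), big.mark = ","),
      "distinct canonical k-mers\n")
  invisible(x)
}

#' Query an index for the transcript sets of given k-mers
#'
#' @param index A `kmer_index`.
#' @param kmers Character vector of length-`k` sequences.
#' @return List of character vectors of transcript ids (empty for k-mers
#'   absent from the index).
#' @export
index_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  lapply(.kmer_index_lookup(index$ptr, kmers),
         function(i) index$ids[i])
}

#' Number of distinct canonical k-mers in an index
#' @param index A `kmer_index`.
#' @return Count of distinct k-mers.
#' @export
index_n_kmers <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  .kmer_index_n_kmers(index$ptr)
}

#' Pseudoalign reads against a k-mer index
#'
#' A read's compatibility set is the intersection of the transcript sets
#' of all its k-mers that are present in the index; k-mers absent from the
#' index (e.g. spanning a sequencing error) are skipped rather than
#' vetoing the read. Reads with an empty intersection, or with no indexed
#' k-mer at all, are counted as unassigned.
#'
#' @param reads Character vector of read sequences (A/C/G/T/N).
#' @param index A `kmer_index`.
#' @return An `ec_counts` object: equivalence classes (transcript id sets)
#'   with read counts, plus the unassigned count.
#' @export
pseudoalign <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  res <- .pseudoalign_cpp(index$ptr, as.character(reads))
  structure(list(ec = res$ec, count = res$count,
                 unassigned = res$unassigned, ids = index$ids),
            class = "ec_counts")
}

#' @export
print.ec_counts <- function(x, ...) {
  cat("<ec_counts>", length(x$ec), "equivalence classes |",
      sum(x$count), "assigned |", x$unassigned, "unassigned\n")
  invisible(x)
}

#' Estimate transcript abundances by expectation-maximization
#'
#' Ambiguous reads are distributed over their equivalence classes by the
#' standard rate-based EM update
#' \deqn{\alpha_t \leftarrow \sum_{ec} c_{ec}
#'   \frac{\alpha_t/\ell_t}{\sum_{t' \in ec} \alpha_{t'}/\ell_{t'}}}
#' from a uniform initialization, until the maximum relative change among
#' non-vanishing transcripts drops below `tol` or `max_iter` is reached.
#' The total estimated count equals the assigned read count after every
#' iteration, and the multinomial log-likelihood is non-decreasing.
#'
#' @param ecs An `ec_counts` object from [pseudoalign()].
#' @param index The `kmer_index` the reads were aligned against.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap; if reached, the result carries
#'   `converged = FALSE` and a warning is raised.
#' @return Abundance table: `data.frame` with `id`, `eff_length`,
#'   `est_counts`; attributes `converged`, `iterations` and `loglik`
#'   (per-iteration log-likelihood trace).
#' @export
em_abundances <- function(ecs, index, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(ecs, "ec_counts"), inherits(index, "kmer_index"))
  ids <- index$ids
  l <- as.numeric(index$eff_lengths[ids])
  n <- length(ids)
  cnt <- ecs$count
  N <- sum(cnt)
  if (length(ecs$ec) == 0L || N == 0) {
    out <- data.frame(id = ids, eff_length = l, est_counts = 0,
                      stringsAsFactors = FALSE)
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    attr(out, "loglik") <- numeric()
    return(out)
  }
  t_idx <- unlist(ecs$ec)
  ec_idx <- rep.int(seq_along(ecs$ec), lengths(ecs$ec))
  # observed-data log-likelihood of the mixture model in which a read
  # from transcript t is uniform over its eff_length positions:
  # P(read with class ec) = sum_{t in ec} (alpha_t/N) / l_t
  loglik <- function(alpha) {
    grp <- rowsum(alpha[t_idx] / l[t_idx], ec_idx)[, 1L]
    sum(cnt * log(grp / N))
  }
  alpha <- rep(N / n, n)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- alpha[t_idx] / l[t_idx]
    denom <- rowsum(r, ec_idx)[, 1L]
    contrib <- cnt[ec_idx] * r / denom[ec_idx]
    upd <- rowsum(contrib, t_idx)
    alpha_new <- numeric(n)
    alpha_new[as.integer(rownames(upd))] <- upd[, 1L]
    ll <- c(ll, loglik(alpha_new))
    live <- alpha_new > 1e-8 * N
    rel <- if (any(live))
      max(abs(alpha_new[live] - alpha[live]) / alpha[live]) else 0
    alpha <- alpha_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations",
            call. = FALSE)
  out <- data.frame(id = ids, eff_length = l, est_counts = alpha,
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "loglik") <- ll
  out
}

#' Add TPM (transcripts per million) to an abundance table
#'
#' \eqn{TPM_t = 10^6 (c_t/\ell_t) / \sum_u (c_u/\ell_u)}. An all-zero
#' table yields all-zero TPM (no division error); otherwise TPM sums to
#' \eqn{10^6}.
#'
#' @param table Abundance table with `est_counts` and `eff_length`.
#' @return The table with a `tpm` column.
#' @export
compute_tpm <- function(table) {
  stopifnot(all(c("id", "eff_length", "est_counts") %in% names(table)),
            all(table$eff_length >= 1))
  rate <- table$est_counts / table$eff_length
  total <- sum(rate)
  table$tpm <- if (total > 0) 1e6 * rate / total else rep(0, nrow(table))
  table
}

#' Call transcripts expressed at a TPM threshold
#'
#' A transcript is called expressed when its TPM strictly exceeds the
#' threshold (default 1 TPM, the conventional background cutoff for
#' RNA-seq expression).
#'
#' @param table Abundance table with a `tpm` column.
#' @param threshold TPM threshold (non-negative).
#' @return `data.frame` with `id`, `tpm`, `expressed`, `threshold`.
#' @export
call_expressed <- function(table, threshold = 1.0) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  stopifnot("tpm" %in% names(table))
  data.frame(id = table$id, tpm = table$tpm,
             expressed = table$tpm > threshold, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Per-transcript fold change between two conditions
#'
#' \eqn{fc_t = (TPM^{treated}_t + p) / (TPM^{control}_t + p)} with a small
#' pseudocount `p` guarding against division by zero at unexpressed
#' transcripts.
#'
#' @param control,treated Abundance tables over the same transcripts.
#' @param pseudocount TPM pseudocount, default 0.01.
#' @return `data.frame` with `id`, `tpm_control`, `tpm_treated`, `fc`.
#' @export
fold_change <- function(control, treated, pseudocount = 0.01) {
  stopifnot("tpm" %in% names(control), "tpm" %in% names(treated))
  if (!identical(sort(control$id), sort(treated$id)))
    stop("control and treated tables cover different transcripts",
         call. = FALSE)
  treated <- treated[match(control$id, treated$id), , drop = FALSE]
  data.frame(id = control$id, tpm_control = control$tpm,
             tpm_treated = treated$tpm,
             fc = (treated$tpm + pseudocount) /
                  (control$tpm + pseudocount),
             stringsAsFactors = FALSE)
}

#' Quantify reads against an index
#'
#' Convenience wrapper: pseudoalign, run EM, normalize to TPM.
#'
#' @param reads Character vector of read sequences.
#' @param index A `kmer_index`.
#' @param tol,max_iter Passed to [em_abundances()].
#' @param condition,cell_line Optional metadata labels attached to the
#'   result.
#' @return Abundance table with `id`, `eff_length`, `est_counts`, `tpm`.
#' @export
quantify <- function(reads, index, tol = 1e-8, max_iter = 1000L,
                     condition = NA_character_,
                     cell_line = NA_character_) {
  ecs <- pseudoalign(reads, index)
  tab <- compute_tpm(em_abundances(ecs, index, tol = tol,
                                   max_iter = max_iter))
  attr(tab, "condition") <- condition
  attr(tab, "cell_line") <- cell_line
  attr(tab, "unassigned") <- ecs$unassigned
  tab
}

#' Compare CDS-only and CDS+UTR index choices on the same reads
#'
#' Quantifies one read set against two indexes built from the same
#' reference but with the inserted allele sequences given either as bare
#' coding sequences or with untranslated regions appended. With reads
#' drawn from full (UTR-bearing) transcripts, the CDS-only index tends to
#' overstate allele TPM: nearly all UTR-overlapping reads still anchor to
#' coding k-mers while the effective length stays short.
#'
#' @param reads Character vector of read sequences.
#' @param cds_index Index with CDS-only allele insertions.
#' @param utr_index Index with CDS+UTR allele insertions.
#' @param allele_ids Ids of the inserted alleles to report; must be
#'   present in both indexes.
#' @return `data.frame` with `id`, `tpm_cds_only`, `tpm_with_utr`,
#'   `ratio` (`tpm_cds_only / tpm_with_utr`, `NA` when both are zero).
#' @export
utr_effect_experiment <- function(reads, cds_index, utr_index,
                                  allele_ids) {
  if (!all(allele_ids %in% cds_index$ids) ||
      !all(allele_ids %in% utr_index$ids))
    stop("allele ids differ between the two indexes", call. = FALSE)
  a <- quantify(reads, cds_index)
  b <- quantify(reads, utr_index)
  ta <- a$tpm[match(allele_ids, a$id)]
  tb <- b$tpm[match(allele_ids, b$id)]
  data.frame(id = allele_ids, tpm_cds_only = ta, tpm_with_utr = tb,
             ratio = ifelse(ta == 0 & tb == 0, NA_real_, ta / tb),
             stringsAsFactors = FALSE)
}

#' Write an abundance table to TSV
#'
#' Columns: `transcript_id`, `eff_length`, `est_counts`, `tpm`,
#' `expressed` (at the given threshold).
#'
#' @param table Abundance table with a `tpm` column.
#' @param path Output TSV path.
#' @param threshold Expression-call TPM threshold.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(table, path, threshold = 1.0) {
  out <- data.frame(transcript_id = table$id,
                    eff_length = table$eff_length,
                    est_counts = table$est_counts, tpm = table$tpm,
                    expressed = table$tpm > threshold)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine vehicle and IFN-gamma calls into an expression table
#'
#' @param vehicle,ifng Abundance tables (with `tpm`) for the unstimulated
#'   and IFN-gamma-stimulated conditions, restricted or not to allele
#'   transcripts.
#' @param ids Transcript ids to report (default: all in `vehicle`).
#' @param threshold TPM threshold for the calls.
#' @return `data.frame` with `allele`, `expressed_vehicle`,
#'   `expressed_ifng`.
#' @export
expression_call_table <- function(vehicle, ifng, ids = vehicle$id,
                                  threshold = 1.0) {
  data.frame(allele = ids,
             expressed_vehicle =
               vehicle$tpm[match(ids, vehicle$id)] > threshold,
             expressed_ifng = ifng$tpm[match(ids, ifng$id)] > threshold,
             stringsAsFactors = FALSE)
}

#' @importFrom utils write.table
NULL
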