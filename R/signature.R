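#' Construct a study matrix for the grade meta-analysis
#'
#' @param study_id Study identifier.
#' @param expression Genes x samples matrix of log2 intensities with gene
#'   rownames.
#' @param grade Per-sample histological grade in `{1, 2, 3}` (Nottingham-
#'   modified Scarff-Bloom-Richardson).
#' @return A `study_matrix` object.
#' @export
study_matrix <- function(study_id, expression, grade) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            ncol(expression) == length(grade))
  grade <- as.integer(grade)
  if (anyNA(grade) || !all(grade %in% 1:3))
    stop("grades must all be in {1, 2, 3}", call. = FALSE)
  if (sum(grade == 3L) < 2L || sum(grade %in% 1:2) < 2L)
    stop("need >= 2 samples in grade 3 and in grade 1-2 for study ",
         study_id, call. = FALSE)
  structure(list(study_id = study_id, expression = expression,
                 grade = grade),
            class = "study_matrix")
}

#' Per-study grade-3 signature
#'
#' For every gene, a Welch two-sample t-test contrasts grade-3 samples
#' against the pooled grade-1/2 group on log2 expression; p-values are
#' Benjamini-Hochberg corrected within the study. A gene enters the study
#' signature when its absolute linear fold change is at least `fc_min`
#' (i.e. \eqn{|log2 FC| \ge log2(fc\_min)}, boundary inclusive) and its
#' FDR q-value is at most `fdr`.
#'
#' @param m A [study_matrix()].
#' @param fc_min Minimum linear fold change, default 2.
#' @param fdr FDR q-value threshold, default 0.01.
#' @return `data.frame` of all genes with `gene`, `log2_fc` (grade 3 minus
#'   grade 1-2 mean log2), `p_value`, `fdr_q`, `passes`.
#' @export
study_signature <- function(m, fc_min = 2, fdr = 0.01) {
  stopifnot(inherits(m, "study_matrix"))
  g3 <- m$grade == 3L
  stats <- t(apply(m$expression, 1L, function(row) {
    tt <- t.test(row[g3], row[!g3], var.equal = FALSE)
    c(lfc = mean(row[g3]) - mean(row[!g3]), p = tt$p.value)
  }))
  q <- p.adjust(stats[, "p"], method = "BH")
  data.frame(gene = rownames(m$expression), log2_fc = stats[, "lfc"],
             p_value = stats[, "p"], fdr_q = q,
             passes = abs(stats[, "lfc"]) >= log2(fc_min) & q <= fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus signature across studies
#'
#' A gene enters the consensus when it passes the per-study thresholds in
#' at least `min_studies` studies *with a consistent direction*; its
#' weight is the mean log2 fold change over its qualifying studies.
#'
#' @param signatures List of per-study [study_signature()] results (or
#'   their `passes` subsets).
#' @param min_studies Minimum number of qualifying studies, default 5.
#' @return A `consensus_signature`: `data.frame` with `gene`, `direction`
#'   (`"up"`/`"down"`), `weight` (mean log2 fold change), `n_studies`.
#' @export
consensus_signature <- function(signatures, min_studies = 5L) {
  if (length(signatures) < min_studies)
    stop("need at least min_studies = ", min_studies, " input studies",
         call. = FALSE)
  passing <- lapply(signatures, function(s) s[s$passes, , drop = FALSE])
  all_genes <- unique(unlist(lapply(passing, function(s) s$gene)))
  rows <- lapply(all_genes, function(g) {
    lfc <- unlist(lapply(passing, function(s) s$log2_fc[s$gene == g]))
    for (dir in c("up", "down")) {
      sel <- if (dir == "up") lfc > 0 else lfc < 0
      if (sum(sel) >= min_studies)
        return(data.frame(gene = g, direction = dir,
                          weight = mean(lfc[sel]),
                          n_studies = sum(sel),
                          stringsAsFactors = FALSE))
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), direction = character(),
                      weight = numeric(), n_studies = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_signature", "data.frame")
  out
}

#' Relative Molecular Grade (RMG) scores
#'
#' Each signature gene is z-scored across the cohort samples
#' (zero-variance genes contribute 0); the raw score of a sample is the
#' weight-weighted sum of its z-scores, and the RMG rescales the raw
#' scores to a 0-100 rank percentile:
#' \deqn{RMG_s = 100 (rank(raw_s) - 0.5)/n}
#' with average ranks at ties. Higher RMG means more grade-3-like (less
#' differentiated); the direction follows the sign convention of the
#' consensus weights (positive weight = higher in grade 3).
#'
#' @param cohort_expression Genes x samples log2 matrix with gene
#'   rownames and sample colnames.
#' @param sig A [consensus_signature()]. Signature genes absent from the
#'   matrix are dropped with a warning.
#' @return `data.frame` with `sample`, `raw`, `rmg`.
#' @export
rmg_scores <- function(cohort_expression, sig) {
  stopifnot(is.matrix(cohort_expression),
            ncol(cohort_expression) >= 2L)
  present <- sig$gene %in% rownames(cohort_expression)
  if (!any(present))
    stop("no signature gene present in the cohort matrix", call. = FALSE)
  if (any(!present))
    warning(sum(!present), " signature gene(s) absent from the cohort ",
            "matrix were dropped", call. = FALSE)
  sig <- sig[present, , drop = FALSE]
  x <- cohort_expression[sig$gene, , drop = FALSE]
  z <- t(apply(x, 1L, function(row) {
    s <- sd(row)
    if (s == 0) rep(0, length(row)) else (row - mean(row)) / s
  }))
  raw <- as.numeric(crossprod(z, sig$weight))
  n <- length(raw)
  rmg <- 100 * (rank(raw, ties.method = "average") - 0.5) / n
  data.frame(sample = colnames(cohort_expression) %||%
               as.character(seq_len(n)),
             raw = raw, rmg = rmg, stringsAsFactors = FALSE)
}

#' Write a consensus signature to TSV
#' @param sig A [consensus_signature()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(sig, path) {
  write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
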