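#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. All stages run on
#' packaged fixtures and seeded simulations by default, so a demo run
#' needs nothing beyond an output directory.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed governing every random stage.
#' @param k,read_length,tpm_threshold Quantification parameters.
#' @param fc_min,fdr,min_studies Meta-analysis parameters.
#' @param n_reads Simulated read count for the quantification stages.
#' @param typings_path,expression_path CSV/TSV inputs for the matching
#'   stage; `NULL` uses the packaged trial fixtures.
#' @param subjects_path,baseline_path,aes_path Clinical-table inputs;
#'   `NULL` uses the packaged trial fixtures.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, k = 21L,
                            read_length = 150L, tpm_threshold = 1.0,
                            fc_min = 2, fdr = 0.01, min_studies = 5L,
                            n_reads = 50000L, typings_path = NULL,
                            expression_path = NULL, subjects_path = NULL,
                            baseline_path = NULL, aes_path = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  for (p in c(typings_path, expression_path, subjects_path,
              baseline_path, aes_path))
    if (!file.exists(p))
      stop("configured input does not exist: ", p, call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 k = as.integer(k), read_length = as.integer(read_length),
                 tpm_threshold = tpm_threshold, fc_min = fc_min,
                 fdr = fdr, min_studies = as.integer(min_studies),
                 n_reads = as.integer(n_reads),
                 typings_path = typings_path,
                 expression_path = expression_path,
                 subjects_path = subjects_path,
                 baseline_path = baseline_path, aes_path = aes_path),
            class = "pipeline_config")
}

.stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed on input ", input, ": ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: build the augmented transcriptome (synthetic
#' reference + allele pairs), quantify simulated vehicle and IFN-gamma
#' read sets, write expression calls, match the trial cohort against the
#' cell line, derive the consensus grade signature from simulated
#' studies, score a simulated cohort with RMG, and summarize the clinical
#' tables. Reruns with the same configuration and seed are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest: stage output paths, parameters and seed
#'   (also written to `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  sc <- sim_config(read_length = config$read_length, k = config$k,
                   n_reads = config$n_reads)
  outputs <- list()

  # 1. augmented transcriptome
  tx <- .stage("build-ref", "synthetic transcriptome", {
    txs <- make_transcriptome(20L, allele_pairs = 2L, config = sc,
                              seed = config$seed)
    plan <- augmentation_plan(txs$removal_ids, txs$alleles, "CDS")
    aug <- build_augmented_transcriptome(txs$reference, plan)
    write_transcripts_fasta(aug, out("augmented.fa"))
    list(aug = aug, alleles = txs$alleles)
  })
  outputs$augmented_fasta <- out("augmented.fa")

  # 2. quantification of vehicle and IFN-gamma simulated read sets
  #    (class II-like alleles induced 20-fold under IFN-gamma)
  quant <- .stage("quantify", outputs$augmented_fasta, {
    index <- build_index(tx$aug, k = config$k,
                         read_length = config$read_length)
    allele_ids <- tx$alleles$id
    base_tpm <- setNames(rep(1, nrow(tx$aug)), tx$aug$id)
    base_tpm[allele_ids] <- c(2000, 500, 0.3, 50)[seq_along(allele_ids)]
    bg <- setdiff(tx$aug$id, allele_ids)
    base_tpm[bg] <- (1e6 - sum(base_tpm[allele_ids])) / length(bg)
    ifng_tpm <- base_tpm
    ifng_tpm[allele_ids[3:4]] <- ifng_tpm[allele_ids[3:4]] * 20
    ifng_tpm <- ifng_tpm / sum(ifng_tpm) * 1e6
    sim_v <- simulate_reads(tx$aug, base_tpm, sc, seed = config$seed + 1L)
    sim_i <- simulate_reads(tx$aug, ifng_tpm, sc, seed = config$seed + 2L)
    tab_v <- quantify(sim_v$reads, index, condition = "vehicle")
    tab_i <- quantify(sim_i$reads, index, condition = "ifng")
    write_abundance_tsv(tab_v, out("abundance_vehicle.tsv"),
                        threshold = config$tpm_threshold)
    write_abundance_tsv(tab_i, out("abundance_ifng.tsv"),
                        threshold = config$tpm_threshold)
    list(v = tab_v, i = tab_i, allele_ids = allele_ids)
  })
  outputs$abundance_vehicle <- out("abundance_vehicle.tsv")
  outputs$abundance_ifng <- out("abundance_ifng.tsv")

  # 3. expression calls for the inserted alleles
  .stage("call", outputs$abundance_ifng, {
    calls <- expression_call_table(quant$v, quant$i,
                                   ids = quant$allele_ids,
                                   threshold = config$tpm_threshold)
    write.table(calls, out("expression_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  outputs$expression_calls <- out("expression_calls.tsv")

  # 4. trial cohort HLA matching (packaged fixtures by default)
  .stage("match", config$typings_path %||% "packaged typing table", {
    typings <- if (is.null(config$typings_path)) load_packaged_typings()
      else { t <- load_typing_table(config$typings_path)
             names(t) <- vapply(t, function(x) x$subject_id, ""); t }
    calls <- if (is.null(config$expression_path))
      load_packaged_expression_calls()
      else load_expression_table(config$expression_path)
    line <- typings[[1L]]
    gate <- expression_gate(calls)
    tab <- cohort_match_table(typings[-1L], line, gate)
    write.csv(tab, out("match_report.csv"), row.names = FALSE)
  })
  outputs$match_report <- out("match_report.csv")

  # 5. consensus grade signature from simulated studies
  sig <- .stage("signature", "simulated grade studies", {
    sim <- simulate_grade_studies(sc, seed = config$seed + 3L)
    sigs <- lapply(sim$studies, study_signature, fc_min = config$fc_min,
                   fdr = config$fdr)
    cs <- consensus_signature(sigs, min_studies = config$min_studies)
    write_signature_tsv(cs, out("signature.tsv"))
    cs
  })
  outputs$signature <- out("signature.tsv")

  # 6. RMG scores on a simulated two-group cohort
  .stage("rmg", outputs$signature, {
    set.seed(config$seed + 4L)
    n_per <- 10L
    genes <- sig$gene
    shift <- outer(sig$weight,
                   c(rep(0, n_per), rep(1, n_per)))
    m <- matrix(rnorm(length(genes) * 2L * n_per, mean = 8, sd = 0.5),
                nrow = length(genes)) + shift
    rownames(m) <- genes
    colnames(m) <- c(sprintf("grade12_%02d", seq_len(n_per)),
                     sprintf("grade3_%02d", seq_len(n_per)))
    scores <- rmg_scores(m, sig)
    write.table(scores, out("rmg.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  outputs$rmg <- out("rmg.tsv")

  # 7. clinical summary
  .stage("clinical-summary", config$subjects_path %||%
           "packaged trial tables", {
    summary <- clinical_summary(
      subjects = load_subject_records(config$subjects_path),
      baseline = load_baseline_table(config$baseline_path),
      adverse_events = load_adverse_events(config$aes_path))
    jsonlite::write_json(summary, out("clinical_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  outputs$clinical_summary <- out("clinical_summary.json")

  manifest <- list(
    package_version = as.character(utils::packageVersion("allovax")),
    seed = config$seed,
    parameters = config[c("k", "read_length", "tpm_threshold", "fc_min",
                          "fdr", "min_studies", "n_reads")],
    outputs = outputs)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
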