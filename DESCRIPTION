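Package: allovax
Title: Allele-Aware HLA Expression Quantification and Whole-Cell
    Immunotherapy Trial Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the molecular and clinical analysis of whole-cell
    breast cancer immunotherapy with the SV-BR-1-GM cell line. Builds a
    line-specific augmented transcriptome in which reference HLA
    transcripts are replaced by the typed alleles of the cell line,
    quantifies allele-level expression from short reads with a k-mer
    pseudoalignment index and an expectation-maximization abundance
    estimator (TPM normalization, 1-TPM expression calls, IFN-gamma fold
    changes, CDS-versus-UTR index comparison), classifies patient-versus-
    line HLA matches at allele and group resolution gated on the line's
    expression calls, derives a consensus tumor-grade gene signature from
    a multi-study meta-analysis together with a per-sample Relative
    Molecular Grade score, and computes the trial's clinical and immune
    summary statistics. Seeded synthetic-data generators make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
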