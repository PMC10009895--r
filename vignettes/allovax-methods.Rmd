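---
title: "Methods: allele-aware HLA quantification, expression-gated matching, and molecular grading"
author: "allovax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware HLA quantification, expression-gated matching, and molecular grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allovax)
```

## Background

SV-BR-1-GM is a GM-CSF-secreting breast cancer cell line used as a
whole-cell immunotherapy. Part of its proposed mechanism of action is
direct antigen presentation: the line carries Class I and Class II HLA
alleles, and patients whose own HLA type matches alleles that the line
both *carries* and *expresses* are hypothesized to benefit most. Testing
that hypothesis requires three things this package implements:

1. **Allele-level expression quantification from RNA-seq.** Standard
   reference transcriptomes carry HLA sequences for alleles the cell
   line does not have; because HLA alleles within a locus are extremely
   similar (91-93% identity for the DRB pairs relevant here), those
   extra sequences absorb reads and corrupt allele-level estimates. The
   package therefore builds a *line-specific augmented transcriptome*:
   all HLA transcripts are removed from the reference and replaced by
   the coding sequences of the alleles the line actually carries, and
   reads are quantified against this index.
2. **Expression-gated donor/line HLA matching**, reproducing the
   trial's per-subject match classification at allele and group
   resolution.
3. **A molecular grade score** (Relative Molecular Grade, RMG) that
   places samples on a differentiation axis learned from a multi-study
   meta-analysis of histologically graded breast tumors.

Alongside these, the package transcribes the trial's clinical tables
(four subjects; exposure, time to progression, survival, adverse
events, baseline demography) and computes the corresponding summary
statistics, plus the serology (percent change in MFI) and qRT-PCR
(delta-delta-Ct) primitives used in the immune-monitoring analyses.

## HLA nomenclature and matching

An HLA allele name is `<locus>*f1:f2:f3:f4` with up to four numeric
fields; the first three fields determine the coding sequence ("CDS
level") and the fourth distinguishes non-coding variants. `parse_allele()`
normalizes names (the `HLA-` prefix is optional; stray typographic
whitespace is stripped) and preserves leading zeros.

Matching rules, per locus:

* **Allele-level match**: some patient allele and some line allele agree
  on their first three fields, *and* the line allele passes the
  expression gate. Comparisons are strict: a 3-field comparison requires
  both alleles to carry at least three fields, so a 2-field typing can
  at most support a group match. Homozygous entries count once.
* **Group match**: no allele-level match, but a pair agrees on the
  first two fields, or failing that the first field; the finest matching
  resolution is reported. The expression gate is applied to group
  matches as well by default (`gate_group = FALSE` disables this; the
  convention is not settled in the field, so it is a switch).
* **Expression gate**: a line allele counts only if it is expressed at
  least following IFN-gamma stimulation — the gate is the OR of the
  vehicle and IFN-gamma calls at the 1-TPM threshold. Sequence matches
  that fail the gate are retained in `expression_gated_out` so reports
  stay auditable.
* Loci typed on only one side (the patients' DRA/DQA1/DPA1 loci were
  not typed) yield `level = "none"` flagged `untyped`, not an error.

A locus can carry an allele-level match *and* a further group-level
correspondence among its other alleles; `MatchResult` keeps both, with
`level` reporting the best.

## Quantification model

### Index

`build_index()` records every length-*k* substring of every transcript
under its canonical form (the smaller of the forward and
reverse-complement 2-bit encodings), mapped to the set of transcripts
containing it. Default `k = 21`: at desk scale (tens of transcripts,
hundreds of thousands of reads) 21-mers give abundant allele-specific
positions across an 8% divergent pair while tolerating substitution
errors; `k` is configurable (odd, 11-31). The effective length of a
transcript is `max(1, length - read_length + 1)` — the number of valid
read start positions, floored so transcripts shorter than a read are
retained.

### Pseudoalignment

A read's compatibility set is the intersection of the transcript sets
of its k-mers *that are present in the index*; absent k-mers (e.g.
spanning a sequencing error) are skipped rather than vetoing the read.
This tolerates the substitution-only error model of the simulator
without error-aware alignment. Reads with no indexed k-mer, or an empty
intersection, are unassigned. Reads are single-end by default: pairing
adds no information to a k-mer compatibility model, and the read length
remains configurable.

### EM abundance estimation

Reads are modeled as draws from a mixture over transcripts in which a
read from transcript $t$ is uniform over its $\ell_t$ start positions,
so the probability of observing equivalence class $ec$ is
$\sum_{t \in ec} (\alpha_t/N)/\ell_t$ with $\alpha_t$ the estimated
counts and $N$ the assigned total. The EM update is

$$\alpha_t \leftarrow \sum_{ec} c_{ec}\,
  \frac{\alpha_t/\ell_t}{\sum_{t' \in ec} \alpha_{t'}/\ell_{t'}},$$

from uniform initialization, with tolerance $10^{-8}$ on the maximum
relative change among non-vanishing transcripts and a 1000-iteration
cap (exceeding it returns a result flagged `converged = FALSE` with a
warning). Totals are conserved exactly at every iteration, and the
observed-data log-likelihood (tracked in the `loglik` attribute) is
non-decreasing. Fully shared classes resolve to equal abundances by the
symmetry of the update. The test suite cross-checks the EM against an
independent dense grid search over the count-fraction simplex on all
small instances.

TPM follows as $10^6 (\alpha_t/\ell_t)/\sum_u (\alpha_u/\ell_u)$;
an all-zero table yields all-zero TPM. A transcript is *called
expressed* when TPM strictly exceeds the threshold; the conventional
cutoff is approximately 1 TPM, so the threshold is a parameter with
default 1.0 rather than a constant. No regression-based normalization
across samples is applied: the analyses here interpret TPM values
directly, and within-sample TPM is sufficient for them.

### CDS-only versus CDS+UTR indexes

Untranslated regions are not reliably known for all alleles, so the
augmented index carries bare coding sequences by default.
`utr_effect_experiment()` quantifies one read set against both index
variants. When the reads derive from full (UTR-bearing) transcripts,
the CDS-only index overstates allele TPM: nearly every UTR-overlapping
read still anchors to coding k-mers and is assigned, while the
effective length stays short, inflating the rate. Including the UTRs
lowers the TPM but leaves genuinely expressed alleles well above the
1-TPM background — the behaviour the experiment is designed to
demonstrate, and the direction the acceptance checks assert. Note that
TPM values from the two indexes are *not* expected to agree even for
pure-CDS reads, because the effective lengths differ; the assigned
counts are what agree in that case.

## Grade signature meta-analysis and RMG

Each study contributes a genes-by-samples matrix of log2 intensities
with per-sample histological grade (1/2/3, Nottingham-modified
Scarff-Bloom-Richardson). Per study, every gene is tested with a Welch
two-sample t-test of grade-3 versus pooled grade-1/2 samples — the
standard two-group microarray contrast, chosen here since the original
platform does not name its test — with Benjamini-Hochberg correction
*within* the study, matching the per-study query design. A gene passes
at $|\log_2 FC| \ge \log_2 2$ (boundary inclusive) and $q \le 0.01$.

The **consensus signature** keeps genes passing in at least 5 of the 7
studies *with a consistent direction* (direction consistency is imposed
here and is configurable, since a gene flipping sign across cohorts is
not a usable grade marker); its weight is the mean log2 fold change
over the qualifying studies.

The **RMG score** of a sample is built from the signature: each
signature gene is z-scored across the cohort (zero-variance genes
contribute 0), the raw score is the weight-weighted sum of z-scores,
and RMG rescales raw scores to a 0-100 rank percentile,
$100\,(\mathrm{rank} - 0.5)/n$ with average ranks at ties. **Higher RMG
means more grade-3-like (less differentiated).** The published RMG
values for specific cell lines depend on a proprietary curated
microarray corpus and a previously normalized dataset that are not
redistributable, so they are not reproduction targets; instead the
score is validated by its properties — invariance to gene-wise affine
rescaling, exact antisymmetry under weight negation, ties of identical
samples at 50, and perfect separation (AUC 1.0) of simulated
grade-3-like from grade-1-like cohorts at a 2-log2 shift with residual
SD 0.5.

## Clinical summaries

Cohort summaries use series-1 values only; one subject's off-protocol
retreatment series is stored in separate columns and never pools into
the cohort statistics. Medians over an even number of subjects are the
mean of the central pair, reported both raw and rounded half-up (94.5
days rounds to 95, 143.5 to 144) — half-up, not banker's rounding,
because that is how the day counts are conventionally reported.
Survival threshold comparisons are strict ("more than 33 months").
The adverse-event tally counts each term once per affected patient and
adds repeat observations on top; grades are carried as free text with
no grading arithmetic. Two dose values in the trial record are
internally inconsistent (irradiation reported as both 100 Gy and
200 Gy; the IFN-gamma dose as both 5 and 50 ng/ml under the same
IU/ml equivalence); they are metadata here and deliberately not
resolved.

```{r clinical}
s <- clinical_summary()
c(median_cycles = s$exposure$inoculations$median_rounded,
  median_days = s$exposure$days_on_treatment$median_rounded,
  median_ttp = s$ttp$median_rounded,
  survivors_over_33mo = s$survival$n_exceeding,
  total_AEs = s$adverse_events$total_events)
```

## What the synthetic data emulate — and what they do not

The generators are seeded and byte-reproducible, and every pipeline
stage is tested exclusively against them:

* `make_allele_pair()` draws a random coding-like sequence and a
  uniformly substituted copy at a target identity (default 0.92,
  matching the 91-93% similarity of the DRB allele pairs that motivate
  allele-aware quantification).
* `make_transcriptome()` adds mutually dissimilar random background
  transcripts and one diverged "reference HLA" decoy per allele pair,
  listed for removal — emulating the replacement of reference HLA
  transcripts by the line's typed alleles.
* `simulate_reads()` draws transcripts proportional to
  TPM × effective length, start positions uniformly, and substitution
  errors per base (default 0.001, no indels).
* `simulate_grade_studies()` plants shared differential genes
  (default 30 at ±2 log2, residual SD 0.5, 40 samples per grade group,
  7 studies) on independent per-study baselines.
* `make_cohort_typings()` constructs typings achieving an exact
  requested match level (and group resolution) per locus, and verifies
  the construction by running it through the matcher.

Deliberately absent: empirical error and quality profiles, indels, GC
and positional bias, codon structure, real IMGT/HLA sequences,
cross-study normalization artifacts, and batch effects. Passing tests
therefore demonstrate the *algorithms* behave as specified under
controlled conditions, not that real 30M-read libraries or real
microarray cohorts would be free of bias; the real study's raw data
live in external archives and are not required here.

### Problem sizes

Simulations are desk-scale by choice: 200,000 single-end 150-base reads
over ~24 transcripts for parameter recovery (the trial's libraries were
~30M reads over a full transcriptome), 7 × 2000-gene studies with 80
samples each for the meta-analysis, and 50 replicates for the null
calibration. At these sizes every transcript with true TPM ≥ 100
receives enough reads that sampling noise sits well inside the ±15%
recovery band, and the full test suite runs in about a minute.

## Numerical choices and edge cases

* EM: uniform initialization; tolerance $10^{-8}$ relative; cap 1000
  iterations; transcripts below $10^{-8} N$ are excluded from the
  convergence criterion so abundances decaying geometrically to zero do
  not stall it.
* Degenerate inputs: all-zero counts give all-zero TPM without
  division errors; an all-N read is unassigned; a transcript shorter
  than the read length keeps effective length 1; zero-variance
  signature genes contribute 0 to RMG; signature genes absent from a
  cohort matrix are dropped with a warning (error only if none remain).
* Ties: fully shared equivalence classes split evenly; RMG ties take
  average ranks, so two identical samples both score exactly 50.
* The expression-call threshold is strict (`tpm > threshold`), so a
  transcript at exactly 1 TPM is not called expressed; the pass rule
  for the signature is inclusive ($\ge$ fold change, $\le$ q), so a
  gene at exactly 2-fold with small q passes.
* Insertion ids in the augmented transcriptome are the canonical
  allele strings, making abundance tables self-describing.

## Known limitations

* No HLA typing from reads, no IMGT/HLA database synchronization, and
  no reconstruction of the ad-hoc read-based deduction of alpha-chain
  alleles (its procedure is unstated and unreliable at low counts).
* No base-level alignment, bias correction, or bootstrap variance; no
  differential-expression testing at the read level.
* No peptide-HLA binding or immunogenicity prediction, and no
  haplotype phasing.
* No survival modelling (no Kaplan-Meier or Cox): with four subjects,
  the clinical module reports medians, ranges and counts only.
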