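# In-code fixtures shared across test files.

# minimal index stand-in for EM tests where only lengths matter
fake_index <- function(eff_lengths) {
  structure(list(ptr = NULL, k = 21L, read_length = 150L,
                 ids = names(eff_lengths),
                 lengths = eff_lengths + 149L,
                 eff_lengths = eff_lengths),
            class = "kmer_index")
}

# equivalence-class counts keyed by transcript ids
make_ecs <- function(ec_ids, counts, ids, unassigned = 0) {
  structure(list(ec = lapply(ec_ids, function(v) sort(match(v, ids))),
                 count = as.numeric(counts), unassigned = unassigned,
                 ids = ids),
            class = "ec_counts")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# cohort fixtures: line typing, patient typings, expression gate
trial_typings <- function() load_packaged_typings()

trial_gate <- function() expression_gate(load_packaged_expression_calls())

# random small EM instance: n transcripts, all singleton classes (for a
# unique ML optimum) plus up to max_extra ambiguous classes
random_em_instance <- function(n, max_extra = 2L) {
  ids <- paste0("t", seq_len(n))
  eff <- setNames(sample(100:900, n), ids)
  subsets <- as.list(ids)
  for (j in seq_len(sample(0:max_extra, 1L))) {
    sz <- sample(2:n, 1L)
    subsets[[length(subsets) + 1L]] <- sort(sample(ids, sz))
  }
  subsets <- unique(subsets)
  counts <- sample(5:200, length(subsets), replace = TRUE)
  list(index = fake_index(eff),
       ecs = make_ecs(subsets, counts, ids))
}
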