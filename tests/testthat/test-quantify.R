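test_that("index k-mer content matches brute-force enumeration", {
  set.seed(501)
  recs <- transcript_records(c("t1", "t2"),
                             c(random_dna(80), random_dna(60)))
  k <- 15
  idx <- build_index(recs, k = k, read_length = 30)
  oracle <- lapply(recs$sequence, canonical_kmers, k = k)
  expect_equal(index_n_kmers(idx), length(unique(unlist(oracle))))
  # each k-mer maps to exactly the transcripts containing it
  for (km in unique(unlist(oracle))) {
    want <- recs$id[vapply(oracle, function(o) km %in% o, TRUE)]
    expect_setequal(index_lookup(idx, km)[[1]], want)
  }
  # reverse-complement queries hit the same canonical entry
  km <- oracle[[1]][1]
  expect_setequal(index_lookup(idx, revcomp_chr(km))[[1]],
                  index_lookup(idx, km)[[1]])
})

test_that("identical sequences share every k-mer; absent k-mers miss", {
  recs <- transcript_records(c("a", "b"),
                             rep("ACGTACGGTTCACGATGCTAGCTAGCTT", 2))
  idx <- build_index(recs, k = 13, read_length = 20)
  for (km in unique(canonical_kmers(recs$sequence[1], 13)))
    expect_setequal(index_lookup(idx, km)[[1]], c("a", "b"))
  expect_length(index_lookup(idx, strrep("A", 13))[[1]], 0L)
})

test_that("a single mid-sequence substitution leaves k allele-specific k-mer positions", {
  set.seed(502)
  k <- 15
  s1 <- random_dna(200)
  # substitute one middle base
  ch <- strsplit(s1, "")[[1]]
  ch[100] <- setdiff(c("A", "C", "G", "T"), ch[100])[1]
  s2 <- paste(ch, collapse = "")
  recs <- transcript_records(c("a1", "a2"), c(s1, s2))
  idx <- build_index(recs, k = k, read_length = 50)
  o1 <- canonical_kmers(s1, k)
  o2 <- canonical_kmers(s2, k)
  # brute force: positions whose k-mer differs between the alleles
  expect_equal(sum(o1 != o2), k)
  for (t in c(1, 2)) {
    own <- if (t == 1) o1 else o2
    other <- if (t == 1) o2 else o1
    specific <- setdiff(own, other)
    for (km in specific)
      expect_equal(index_lookup(idx, km)[[1]], recs$id[t])
  }
})

test_that("index construction validates inputs", {
  recs <- transcript_records("short", "ACGTACGT")
  expect_error(build_index(recs, k = 21), "short")
  long <- transcript_records("ok", random_dna(100))
  expect_error(build_index(long, k = 20), "odd")
  expect_error(build_index(long, k = 9), "between")
})

test_that("pseudoalignment forms the expected compatibility classes", {
  set.seed(503)
  shared <- random_dna(120)
  u1 <- random_dna(100)
  u2 <- random_dna(100)
  recs <- transcript_records(c("t1", "t2"),
                             c(paste0(u1, shared), paste0(u2, shared)))
  idx <- build_index(recs, k = 21, read_length = 50)
  reads <- c(substr(u1, 10, 59),             # unique to t1
             substr(shared, 30, 79),         # shared region
             random_dna(50),                 # alien
             strrep("N", 50))                # all ambiguous
  ecs <- pseudoalign(reads, idx)
  got <- lapply(ecs$ec, function(i) idx$ids[i])
  expect_true(any(vapply(got, function(g) identical(g, "t1"), TRUE)))
  expect_true(any(vapply(got, function(g)
    setequal(g, c("t1", "t2")), TRUE)))
  expect_equal(ecs$unassigned, 2)
  expect_equal(sum(ecs$count) + ecs$unassigned, length(reads))
  expect_error(pseudoalign("ACGTXACGT", idx), "outside")
})

test_that("a read with one sequencing error is still assigned (k-mer skipping)", {
  set.seed(504)
  recs <- transcript_records("t1", random_dna(300))
  idx <- build_index(recs, k = 21, read_length = 100)
  read <- substr(recs$sequence, 50, 149)
  ch <- strsplit(read, "")[[1]]
  ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
  ecs <- pseudoalign(paste(ch, collapse = ""), idx)
  expect_equal(sum(ecs$count), 1)
  expect_equal(ecs$unassigned, 0)
})

test_that("EM solves unambiguous and symmetric instances exactly", {
  # one transcript takes all reads
  i1 <- fake_index(setNames(500, "t1"))
  e1 <- make_ecs(list("t1"), 1000, "t1")
  expect_equal(em_abundances(e1, i1)$est_counts, 1000)
  # fully shared class over equal lengths splits evenly by symmetry
  i2 <- fake_index(setNames(c(400, 400), c("t1", "t2")))
  e2 <- make_ecs(list(c("t1", "t2")), 100, c("t1", "t2"))
  expect_equal(em_abundances(e2, i2)$est_counts, c(50, 50))
})

test_that("EM matches the grid-search ML oracle on the canonical instance", {
  idx <- fake_index(setNames(c(300, 300), c("t1", "t2")))
  ecs <- make_ecs(list("t1", c("t1", "t2")), c(30, 70), c("t1", "t2"))
  fit <- em_abundances(ecs, idx)
  rel <- fit$est_counts / sum(fit$est_counts)
  oracle <- grid_ml_abundance(lapply(ecs$ec, identity), ecs$count,
                              unname(idx$eff_lengths))
  # the ML solution loads everything on t1 (the shared class is free)
  expect_equal(oracle, c(1, 0), tolerance = 1e-3)
  expect_equal(rel, oracle, tolerance = 1e-3)
})

test_that("EM agrees with the oracle across random small instances", {
  set.seed(505)
  for (rep in 1:12) {
    inst <- random_em_instance(sample(2:3, 1))
    fit <- em_abundances(inst$ecs, inst$index)
    rel <- fit$est_counts / sum(fit$est_counts)
    oracle <- grid_ml_abundance(inst$ecs$ec, inst$ecs$count,
                                unname(inst$index$eff_lengths))
    expect_equal(rel, oracle, tolerance = 2e-3)
    # conservation and monotone log-likelihood
    expect_equal(sum(fit$est_counts), sum(inst$ecs$count),
                 tolerance = 1e-9)
    ll <- attr(fit, "loglik")
    expect_true(all(diff(ll) > -1e-9))
  }
})

test_that("EM flags non-convergence without losing mass", {
  idx <- fake_index(setNames(c(100, 200, 300), paste0("t", 1:3)))
  ecs <- make_ecs(list("t1", c("t1", "t2"), c("t2", "t3")),
                  c(10, 40, 50), paste0("t", 1:3))
  expect_warning(fit <- em_abundances(ecs, idx, max_iter = 2L),
                 "converge")
  expect_false(attr(fit, "converged"))
  expect_equal(sum(fit$est_counts), 100, tolerance = 1e-9)
})

test_that("TPM normalization follows the closed form", {
  tab <- data.frame(id = c("a", "b"), eff_length = c(100, 200),
                    est_counts = c(10, 10))
  out <- compute_tpm(tab)
  expect_equal(out$tpm, c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-8)
  expect_equal(sum(out$tpm), 1e6)
  one <- compute_tpm(data.frame(id = "a", eff_length = 50,
                                est_counts = 7))
  expect_equal(one$tpm, 1e6)
  zero <- compute_tpm(data.frame(id = c("a", "b"),
                                 eff_length = c(10, 10),
                                 est_counts = c(0, 0)))
  expect_equal(zero$tpm, c(0, 0))
})

test_that("expression calls use a strict threshold", {
  tab <- data.frame(id = c("a", "b", "c"), eff_length = 1,
                    est_counts = 1, tpm = c(0.99, 1.0, 1.01))
  calls <- call_expressed(tab, threshold = 1.0)
  expect_equal(calls$expressed, c(FALSE, FALSE, TRUE))
  expect_error(call_expressed(tab, threshold = -1), "non-negative")
})

test_that("fold changes are ratio-of-TPM with a pseudocount", {
  a <- data.frame(id = c("x", "y"), tpm = c(10, 0))
  b <- data.frame(id = c("x", "y"), tpm = c(100, 0))
  fc <- fold_change(a, b, pseudocount = 1e-9)
  expect_equal(fc$fc[1], 10, tolerance = 1e-6)
  expect_equal(fc$fc[2], 1)
  expect_equal(fold_change(a, a)$fc, c(1, 1))
  expect_error(fold_change(a, data.frame(id = "x", tpm = 1)),
               "different transcripts")
})

test_that("UTR comparison validates ids and handles zero reads", {
  set.seed(506)
  recs <- transcript_records(c("bg", "al"),
                             c(random_dna(300), random_dna(300)))
  idx <- build_index(recs, k = 21, read_length = 50)
  out <- utr_effect_experiment(character(), idx, idx, "al")
  expect_equal(out$tpm_cds_only, 0)
  expect_equal(out$tpm_with_utr, 0)
  expect_true(is.na(out$ratio))
  expect_error(utr_effect_experiment(character(), idx, idx, "missing"),
               "differ")
})
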