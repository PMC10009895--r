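test_that("a planted study is recovered with BH-level false positives", {
  set.seed(601)
  sc <- sim_config(study = list(n_studies = 1L, n_genes = 2000L,
                                samples_per_group = 40L, n_planted = 20L,
                                planted_lfc = 2, noise_sd = 0.5))
  sim <- simulate_grade_studies(sc)
  sig <- study_signature(sim$studies[[1]], fc_min = 2, fdr = 0.01)
  hits <- sig$gene[sig$passes]
  expect_true(all(sim$truth$gene %in% hits))
  expect_lte(length(setdiff(hits, sim$truth$gene)), 2L)
  # recovered directions match the planted ones
  m <- merge(sig[sig$passes, ], sim$truth, by = "gene")
  expect_true(all(sign(m$log2_fc.x) == sign(m$log2_fc.y)))
})

test_that("study matrices enforce grade groups of at least two", {
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("g", 1:4), NULL))
  expect_error(study_matrix("s", m, c(3, rep(1, 9))), ">= 2 samples")
  expect_error(study_matrix("s", m, c(rep(3, 9), 4)), "grades")
})

test_that("pass criteria are inclusive at the fold-change and FDR bounds", {
  set.seed(602)
  sc <- sim_config(study = list(n_studies = 1L, n_genes = 300L,
                                samples_per_group = 30L, n_planted = 10L,
                                planted_lfc = 1.4, noise_sd = 0.4))
  sig <- study_signature(simulate_grade_studies(sc)$studies[[1]])
  expect_identical(sig$passes,
                   abs(sig$log2_fc) >= log2(2) & sig$fdr_q <= 0.01)
  expect_true(all(sig$fdr_q >= sig$p_value))
})

test_that("consensus requires min_studies same-direction hits", {
  fake <- function(genes, lfc) {
    data.frame(gene = genes, log2_fc = lfc, p_value = 1e-6,
               fdr_q = 1e-5, passes = TRUE, stringsAsFactors = FALSE)
  }
  sigs <- c(
    lapply(1:4, function(i) fake(c("gA", "gC"), c(2, 1.5))),
    lapply(1:3, function(i) fake(c("gB", "gC"), c(-2, -1.5))))
  # 7 studies: gA up in 4 (excluded), gB down in 3 (excluded),
  # gC up in 4 and down in 3 (direction-inconsistent, excluded)
  cs <- consensus_signature(sigs, min_studies = 5L)
  expect_equal(nrow(cs), 0L)
  # gA present in 5 studies, same direction -> included, weight = mean
  sigs5 <- c(sigs, lapply(1:2, function(i) fake("gA", 3)))
  cs5 <- consensus_signature(sigs5, min_studies = 5L)
  expect_equal(cs5$gene, "gA")
  expect_equal(cs5$direction, "up")
  expect_equal(cs5$n_studies, 6L)
  expect_equal(cs5$weight, mean(c(2, 2, 2, 2, 3, 3)))
  expect_error(consensus_signature(sigs[1:4], min_studies = 5L),
               "at least")
})

test_that("seven simulated studies yield exactly the planted consensus", {
  sc <- sim_config()
  sim <- simulate_grade_studies(sc, seed = 603)
  sigs <- lapply(sim$studies, study_signature)
  cs <- consensus_signature(sigs, min_studies = 5L)
  expect_setequal(cs$gene, sim$truth$gene)
  m <- merge(as.data.frame(cs), sim$truth, by = "gene")
  expect_true(all(m$direction.x == m$direction.y))
  expect_equal(m$weight, m$log2_fc, tolerance = 0.1)
  # invariance to study input order
  cs_rev <- consensus_signature(rev(sigs), min_studies = 5L)
  expect_equal(as.data.frame(cs), as.data.frame(cs_rev))
})

test_that("BH correction agrees with the brute-force step-up rule", {
  set.seed(604)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(p.adjust(p, "BH") <= q, bh_reject_oracle(p, q))
  }
})

test_that("RMG ties identical samples at 50 and spans (0, 100)", {
  sig <- structure(data.frame(gene = paste0("g", 1:5),
                              direction = "up", weight = 1,
                              n_studies = 5L),
                   class = c("consensus_signature", "data.frame"))
  m <- matrix(rnorm(5), nrow = 5, ncol = 2,
              dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  out <- rmg_scores(m, sig)
  expect_equal(out$rmg, c(50, 50))
  set.seed(605)
  m2 <- matrix(rnorm(5 * 20), nrow = 5,
               dimnames = list(paste0("g", 1:5), NULL))
  out2 <- rmg_scores(m2, sig)
  expect_true(all(out2$rmg > 0 & out2$rmg < 100))
})

test_that("RMG is invariant to gene-wise affine rescaling", {
  set.seed(606)
  sig <- structure(data.frame(gene = paste0("g", 1:8),
                              direction = rep(c("up", "down"), 4),
                              weight = rep(c(1.5, -1.2), 4),
                              n_studies = 5L),
                   class = c("consensus_signature", "data.frame"))
  m <- matrix(rnorm(8 * 12), nrow = 8,
              dimnames = list(paste0("g", 1:8), NULL))
  a <- runif(8, 0.5, 3)
  b <- rnorm(8)
  m2 <- m * a + b
  expect_equal(rmg_scores(m, sig)$rmg, rmg_scores(m2, sig)$rmg)
})

test_that("flipping all weights reverses the RMG ranking exactly", {
  set.seed(607)
  sig <- structure(data.frame(gene = paste0("g", 1:6), direction = "up",
                              weight = runif(6, 0.5, 2), n_studies = 5L),
                   class = c("consensus_signature", "data.frame"))
  m <- matrix(rnorm(6 * 9), nrow = 6,
              dimnames = list(paste0("g", 1:6), NULL))
  fwd <- rmg_scores(m, sig)
  sig$weight <- -sig$weight
  rev <- rmg_scores(m, sig)
  expect_equal(rev$rmg, 100 - fwd$rmg)
})

test_that("RMG separates shifted grade-3-like samples perfectly", {
  set.seed(608)
  sc <- sim_config()
  sim <- simulate_grade_studies(sc, seed = 608)
  cs <- consensus_signature(lapply(sim$studies, study_signature))
  n_per <- 12L
  m <- matrix(rnorm(nrow(cs) * 2 * n_per, mean = 8, sd = 0.5),
              nrow = nrow(cs),
              dimnames = list(cs$gene,
                              c(sprintf("g12_%02d", 1:n_per),
                                sprintf("g3_%02d", 1:n_per))))
  # grade-3-like samples shifted by the planted per-gene log2 fold change
  m[, (n_per + 1):(2 * n_per)] <-
    m[, (n_per + 1):(2 * n_per)] + cs$weight
  out <- rmg_scores(m, cs)
  g3 <- grepl("^g3", out$sample)
  expect_equal(auc_score(out$rmg[g3], out$rmg[!g3]), 1.0)
})

test_that("missing and degenerate signature genes are handled", {
  sig <- structure(data.frame(gene = c("g1", "g2", "gX"),
                              direction = "up", weight = 1,
                              n_studies = 5L),
                   class = c("consensus_signature", "data.frame"))
  m <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_warning(out <- rmg_scores(m, sig), "dropped")
  expect_equal(nrow(out), 4L)
  # zero-variance g2 contributes nothing; ranking driven by g1
  expect_equal(order(out$raw), 1:4)
  m0 <- matrix(rnorm(4), nrow = 2,
               dimnames = list(c("a", "b"), NULL))
  expect_error(suppressWarnings(rmg_scores(m0, sig)), "no signature gene")
})
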