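# Independent brute-force oracles used to cross-check the implementation.

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

canonical_chr <- function(s) {
  rc <- revcomp_chr(s)
  if (s <= rc) s else rc
}

# all k-mers of a sequence by plain substring extraction
enumerate_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  vapply(seq_len(n - k + 1L), function(i) substr(seq, i, i + k - 1L), "")
}

canonical_kmers <- function(seq, k) {
  vapply(enumerate_kmers(seq, k), canonical_chr, "", USE.NAMES = FALSE)
}

# maximum-likelihood relative counts by two-stage dense grid search over
# the count-fraction simplex (w = alpha/N), for 1-3 transcripts, under
# the position-uniform read model P(class ec) = sum_{t in ec} w_t/l_t;
# independent of the EM path it cross-checks
grid_ml_abundance <- function(ec, count, eff_length) {
  n <- length(eff_length)
  ll_of <- function(P) {
    Q <- P / rep(eff_length, each = nrow(P))
    ll <- numeric(nrow(P))
    for (j in seq_along(ec))
      ll <- ll + count[j] * log(rowSums(Q[, ec[[j]], drop = FALSE]))
    ll
  }
  simplex_grid <- function(lo, hi, step) {
    if (n == 1L) return(matrix(1, 1L, 1L))
    s1 <- seq(max(0, lo[1L]), min(1, hi[1L]), by = step)
    if (n == 2L) {
      P <- cbind(s1, 1 - s1)
    } else {
      s2 <- seq(max(0, lo[2L]), min(1, hi[2L]), by = step)
      P <- as.matrix(expand.grid(s1, s2))
      P <- cbind(P, 1 - rowSums(P))
      P <- P[P[, 3L] >= -1e-12, , drop = FALSE]
      P[, 3L] <- pmax(P[, 3L], 0)
    }
    P
  }
  P <- simplex_grid(rep(0, n), rep(1, n), 0.005)
  best <- P[which.max(ll_of(P)), ]
  P <- simplex_grid(best - 0.01, best + 0.01, 1e-4)
  unname(P[which.max(ll_of(P)), ])
}

# Benjamini-Hochberg step-up rejections, decided directly from the
# definition (largest k with p_(k) <= q k/m)
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= q * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# sort-based median (mean of central pair for even n)
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# rank-sum AUC of scores for positive vs negative groups
auc_score <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
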