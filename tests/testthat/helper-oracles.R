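# Fixture builders and independent brute-force oracles used across tests.

# quick genotype_matrix from a dosage matrix, one chromosome
toy_geno <- function(d, ids = NULL) {
  d <- as.matrix(d)
  if (!is.null(ids)) rownames(d) <- ids
  genotype_matrix(d, data.frame(chrom = "1", pos = seq_len(ncol(d)),
                                ref = "A", alt = "T"))
}

# Nei (1972) standard distance between two diploid genotype vectors,
# computed naively locus by locus from allele-frequency vectors (0/0.5/1).
nei_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  px <- x[ok] / 2; py <- y[ok] / 2
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  jxy <- mean(px * py + (1 - px) * (1 - py))
  -log(jxy / sqrt(jx * jy))
}

# Expected IBS-state probabilities at one locus given an IBD state, by
# exhaustive enumeration of ordered without-replacement allele draws from a
# pool with `alt` ALT alleles among `n` total.  IBD0 draws 4 alleles, IBD1
# draws 3 (one shared); IBS states computed from the resulting genotypes.
ibs_given_ibd_oracle <- function(alt, n) {
  pool <- c(rep(1, alt), rep(0, n - alt))
  idx <- seq_len(n)
  p0 <- c(0, 0, 0)   # P(IBS = 0,1,2 | IBD0)
  cnt0 <- 0
  for (a in idx) for (b in idx) for (cc in idx) for (d in idx) {
    if (length(unique(c(a, b, cc, d))) < 4) next
    g1 <- pool[a] + pool[b]; g2 <- pool[cc] + pool[d]
    ibs <- 2 - abs(g1 - g2)
    p0[ibs + 1] <- p0[ibs + 1] + 1
    cnt0 <- cnt0 + 1
  }
  p1 <- c(0, 0, 0)
  cnt1 <- 0
  for (s in idx) for (a in idx) for (b in idx) {
    if (length(unique(c(s, a, b))) < 3) next
    g1 <- pool[s] + pool[a]; g2 <- pool[s] + pool[b]
    ibs <- 2 - abs(g1 - g2)
    p1[ibs + 1] <- p1[ibs + 1] + 1
    cnt1 <- cnt1 + 1
  }
  list(ibd0 = p0 / cnt0, ibd1 = p1 / cnt1, ibd2 = c(0, 0, 1))
}

# Weir & Cockerham (1984) a/b/c for one biallelic locus, straight from the
# published formulas (independent re-derivation used as the F_ST oracle).
wc_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

fst_oracle <- function(g, labels) {
  labs <- unique(labels)
  stopifnot(length(labs) == 2)
  sa <- 0; sabc <- 0
  for (l in seq_len(ncol(g$dosages))) {
    x1 <- g$dosages[labels == labs[1], l]
    x2 <- g$dosages[labels == labs[2], l]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (!length(x1) || !length(x2)) next
    n_i <- c(length(x1), length(x2))
    p_i <- c(mean(x1) / 2, mean(x2) / 2)
    h_i <- c(mean(x1 == 1), mean(x2 == 1))
    comp <- wc_oracle(n_i, p_i, h_i)
    if (anyNA(comp)) next
    sa <- sa + comp["a"]; sabc <- sabc + sum(comp)
  }
  unname(sa / sabc)
}

# Quadratic-time reference LD pruner: same window/step/tie rules as
# ld_prune(), re-implemented directly without the incremental bookkeeping.
ld_prune_oracle <- function(g, window = 50, step = 5, r2_max = 0.5) {
  keep <- rep(TRUE, ncol(g$dosages))
  maf <- minor_allele_freq(g)
  for (ch in unique(g$markers$chrom)) {
    idx <- which(g$markers$chrom == ch)
    starts <- unique(c(seq(1, max(1, length(idx) - 1), by = step)))
    for (start in starts) {
      if (start > length(idx)) break
      win <- idx[start:min(start + window - 1, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        r2 <- suppressWarnings(
          stats::cor(g$dosages[, act, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        if (all(r2 <= r2_max)) break
        hit <- which(r2 > r2_max, arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        i <- act[hit[1, 1]]; j <- act[hit[1, 2]]
        drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
        keep[drop] <- FALSE
      }
      if (start + window - 1 >= length(idx)) break
    }
  }
  which(keep)
}

# Kruskal-Wallis H for two groups of 3 by exhaustive enumeration of rank
# assignments (used as the small-sample oracle).
kw_h_oracle <- function(v, labels) {
  rk <- rank(v)
  n <- length(v)
  groups <- split(rk, labels)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(r) length(r) * mean(r)^2, 0) * 1) -
    3 * (n + 1)
  # tie correction
  t_ <- table(v)
  ct <- 1 - sum(t_^3 - t_) / (n^3 - n)
  h / ct
}
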