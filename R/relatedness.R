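#' Nei (1972) standard genetic distance between accessions
#'
#' Each accession is treated as a one-individual population with per-locus
#' allele frequencies 0, 0.5 or 1 from its genotype.  For a pair, the gene
#' identities J_x, J_y and J_xy are averaged over loci non-missing in both
#' accessions, the normalised identity is I = J_xy / sqrt(J_x J_y) and
#' D = -ln I.  Identical genotypes give D = 0.  When J_xy = 0 the distance is
#' infinite and stored as the cap `inf_cap`; a pair with no overlapping loci
#' gets `NA`.
#'
#' @param g a [genotype_matrix].
#' @param inf_cap numeric value used to represent infinite distance
#'   (default 1e9).
#' @return symmetric numeric matrix of distances with accession IDs as
#'   dimnames.
#' @export
nei_distance <- function(g, inf_cap = 1e9) {
  x <- g$dosages
  storage.mode(x) <- "double"
  m <- (!is.na(x)) * 1
  p <- x / 2
  p[is.na(p)] <- 0
  qq <- (1 - x / 2)
  qq[is.na(qq)] <- 0
  # J_xy over shared loci: sum_l m_i m_j (p_i p_j + q_i q_j)
  jxy <- tcrossprod(p) + tcrossprod(qq)
  # per-pair J_x over the pair's shared loci: sum_l m_j * [m_i (p_i^2+q_i^2)]
  s <- m * (p^2 + qq^2)
  jx <- tcrossprod(s, m)     # jx[i, j] = J_x over loci shared with j
  nshared <- tcrossprod(m)
  ident <- jxy / sqrt(jx * t(jx))
  ident <- pmin(ident, 1)
  d <- -log(ident)
  d[ident <= 0] <- inf_cap
  d[nshared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(g$accession_ids, g$accession_ids)
  d
}

#' VanRaden (method 1) genomic relationship matrix
#'
#' G = Z Z' / (2 * sum_j p_j (1 - p_j)) where Z is the dosage matrix centred
#' by twice the panel allele frequency.  Monomorphic markers contribute
#' nothing to the denominator.  Missing dosages are replaced by the marker
#' mean (centred contribution zero).
#'
#' @param g a [genotype_matrix].
#' @return symmetric numeric matrix with accession IDs as dimnames.
#' @export
vanraden_grm <- function(g) {
  x <- g$dosages
  storage.mode(x) <- "double"
  p <- allele_freq(g)
  usable <- !is.nan(p)
  if (!any(usable)) stop("no markers with observed genotypes", call. = FALSE)
  x <- x[, usable, drop = FALSE]
  p <- p[usable]
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers monomorphic: GRM denominator is zero",
                       call. = FALSE)
  z <- sweep(x, 2, 2 * p)
  z[is.na(z)] <- 0
  gm <- tcrossprod(z) / denom
  dimnames(gm) <- list(g$accession_ids, g$accession_ids)
  gm
}

# Exact finite-sample expected IBS-state probabilities per marker, from
# without-replacement allele draws out of the panel's observed allele pool.
# For a marker with c ALT alleles among N observed alleles, the probability
# of each IBS state given an IBD state is a ratio of falling factorials:
# drawing 4 (IBD0), 3 (IBD1) alleles without replacement is the unbiased
# finite-sample analogue of the Hardy-Weinberg plug-in expectations.
ibs_state_expectations <- function(alt_count, n_alleles) {
  c_ <- alt_count; N <- n_alleles; r <- N - c_
  ff <- function(x, k) {
    out <- rep(1, length(x))
    for (i in seq_len(k)) out <- out * (x - i + 1)
    out
  }
  n4 <- ff(N, 4); n3 <- ff(N, 3)
  e <- list(
    p00 = 2 * ff(c_, 2) * ff(r, 2) / n4,
    p10 = (4 * ff(c_, 3) * r + 4 * c_ * ff(r, 3)) / n4,
    p20 = (ff(c_, 4) + ff(r, 4) + 4 * ff(c_, 2) * ff(r, 2)) / n4,
    p11 = (2 * ff(c_, 2) * r + 2 * ff(r, 2) * c_) / n3,
    p21 = (ff(c_, 3) + ff(r, 3) + c_ * ff(r, 2) + r * ff(c_, 2)) / n3
  )
  # markers with too few observed alleles carry no information
  bad <- N < 4
  for (nm in names(e)) e[[nm]][bad] <- 0
  e$informative <- !bad
  e
}

#' Method-of-moments genome-wide IBD estimation
#'
#' For every unordered accession pair, counts the loci in IBS state 0, 1 and
#' 2 (loci non-missing in both members), forms finite-sample expectations of
#' those counts under IBD states 0, 1 and 2 from the panel's observed allele
#' counts, and solves the moment equations for P(IBD = 0, 1, 2).  Estimates
#' are clamped to [0, 1], renormalised to sum 1, and summarised as
#' pi-hat = Z1/2 + Z2.  IBS is also reported as the mean allele-sharing
#' fraction.
#'
#' @param g a [genotype_matrix], ideally LD-pruned so loci are
#'   quasi-independent.
#' @param min_overlap pairs with fewer overlapping markers are flagged
#'   `low_confidence` (default 20).
#' @return data.frame with columns `id1`, `id2`, `ibs`, `z0`, `z1`, `z2`,
#'   `pi_hat`, `n_overlap`, `low_confidence`.
#' @export
mom_ibd <- function(g, min_overlap = 20) {
  x <- g$dosages
  n <- nrow(x); L <- ncol(x)
  ids <- g$accession_ids
  m <- (!is.na(x)) * 1
  alt <- colSums(x, na.rm = TRUE)
  nal <- 2 * colSums(m)
  e <- ibs_state_expectations(alt, nal)
  # loci with fewer than 4 observed alleles carry no moment information;
  # exclude them from both observed and expected counts
  m[, !e$informative] <- 0

  i0 <- (x == 0L & m == 1) * 1
  i1 <- (x == 1L & m == 1) * 1
  i2 <- (x == 2L & m == 1) * 1
  i0[is.na(i0)] <- 0; i1[is.na(i1)] <- 0; i2[is.na(i2)] <- 0

  n_shared <- tcrossprod(m)
  obs0 <- tcrossprod(i0, i2); obs0 <- obs0 + t(obs0)       # opposite homozygotes
  obs2 <- tcrossprod(i0) + tcrossprod(i1) + tcrossprod(i2) # identical genotypes
  obs1 <- n_shared - obs0 - obs2

  # per-pair expected counts: sum over loci shared by the pair
  psum <- function(v) tcrossprod(sweep(m, 2, v, `*`), m)
  E00 <- psum(e$p00); E10 <- psum(e$p10); E20 <- psum(e$p20)
  E11 <- psum(e$p11); E21 <- psum(e$p21)
  Linf <- n_shared   # informative loci shared by the pair

  ut <- upper.tri(n_shared)
  ii <- row(n_shared)[ut]; jj <- col(n_shared)[ut]

  z0 <- ifelse(E00[ut] > 0, obs0[ut] / E00[ut], 0)
  z1 <- ifelse(E11[ut] > 0, (obs1[ut] - z0 * E10[ut]) / E11[ut], 0)
  z2 <- ifelse(Linf[ut] > 0,
               (obs2[ut] - z0 * E20[ut] - z1 * E21[ut]) / Linf[ut], 0)
  zm <- cbind(z0, z1, z2)
  zm[zm < 0] <- 0
  zm[zm > 1] <- 1
  s <- rowSums(zm)
  s[s == 0] <- 1
  zm <- zm / s
  pihat <- zm[, 2] / 2 + zm[, 3]

  ibs <- ifelse(n_shared[ut] > 0,
                (obs1[ut] * 1 + obs2[ut] * 2) / (2 * n_shared[ut]), NA_real_)

  data.frame(id1 = ids[ii], id2 = ids[jj],
             ibs = ibs,
             z0 = zm[, 1], z1 = zm[, 2], z2 = zm[, 3],
             pi_hat = pihat,
             n_overlap = n_shared[ut],
             low_confidence = n_shared[ut] < min_overlap,
             stringsAsFactors = FALSE)
}

#' Full pairwise relatedness table
#'
#' Combines Nei distance, GRM off-diagonals and method-of-moments IBD into
#' one pair table.  The IBD metrics may be computed on a different (pruned)
#' marker set than distance and GRM.
#'
#' @param g a [genotype_matrix] for distance and GRM.
#' @param g_pruned a [genotype_matrix] (same accessions) for IBD; defaults to
#'   `g`.
#' @param min_overlap passed to [mom_ibd()].
#' @return data.frame with columns `id1`, `id2`, `d`, `g`, `ibs`, `z0`, `z1`,
#'   `z2`, `pi_hat`, `n_overlap`, `low_confidence`.
#' @export
pair_relatedness <- function(g, g_pruned = g, min_overlap = 20) {
  stopifnot(identical(g$accession_ids, g_pruned$accession_ids))
  d <- nei_distance(g)
  gm <- vanraden_grm(g)
  ibd <- mom_ibd(g_pruned, min_overlap = min_overlap)
  ut <- upper.tri(d)
  out <- data.frame(id1 = ibd$id1, id2 = ibd$id2,
                    d = d[ut], g = gm[ut],
                    ibd[, c("ibs", "z0", "z1", "z2", "pi_hat",
                            "n_overlap", "low_confidence")],
                    stringsAsFactors = FALSE)
  out
}

#' Percentage of related pairs per collection combination
#'
#' For collections A and B, the percentage of pairs with pi-hat above zero
#' out of all possible pairs: |A| * |B| pairs for A != B and choose(|A|, 2)
#' within a collection.  Singleton within-collection cells are `NA`.
#'
#' @param pairs data.frame with `id1`, `id2`, `pi_hat` (e.g. from
#'   [mom_ibd()] or [pair_relatedness()]).
#' @param passport passport data.frame with `accession_id` and `collection`.
#' @return symmetric numeric matrix of percentages, collections as dimnames.
#' @export
percent_ibd_by_collection <- function(pairs, passport) {
  coll <- stats::setNames(passport$collection, passport$accession_id)
  if (any(is.na(coll[pairs$id1])) || any(is.na(coll[pairs$id2]))) {
    stop("pair members missing from passport", call. = FALSE)
  }
  labs <- sort(unique(passport$collection))
  sizes <- table(factor(passport$collection, levels = labs))
  c1 <- coll[pairs$id1]; c2 <- coll[pairs$id2]
  a <- pmin(c1, c2); b <- pmax(c1, c2)
  hit <- pairs$pi_hat > 0
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    A <- labs[i]; B <- labs[j]
    tot <- if (i == j) choose(sizes[[A]], 2) else sizes[[A]] * sizes[[B]]
    if (tot == 0) next
    cnt <- sum(hit & a == min(A, B) & b == max(A, B))
    out[i, j] <- out[j, i] <- 100 * cnt / tot
  }
  out
}

#' Per-region density summaries of pi-hat
#'
#' A pair belongs to a region when both members share that region label.
#' Regions with fewer than two accessions (no pairs) are skipped.
#'
#' @param pairs data.frame with `id1`, `id2`, `pi_hat`.
#' @param passport passport data.frame with `accession_id` and `region`.
#' @param bw density bandwidth passed to [stats::density()] (default "nrd0").
#' @return named list per region: `n_pairs`, `density` (a `density` object)
#'   and `peaks` (pi-hat locations of local density maxima, highest first).
#' @export
ibd_density_by_region <- function(pairs, passport, bw = "nrd0") {
  reg <- stats::setNames(passport$region, passport$accession_id)
  r1 <- reg[pairs$id1]; r2 <- reg[pairs$id2]
  same <- !is.na(r1) & !is.na(r2) & r1 == r2
  out <- list()
  for (r in sort(unique(passport$region))) {
    v <- pairs$pi_hat[same & r1 == r]
    if (length(v) < 2) next
    dn <- if (stats::var(v) == 0) {
      stats::density(v, bw = 0.01, from = -0.05, to = 1.05)
    } else stats::density(v, bw = bw, from = -0.05, to = 1.05)
    y <- dn$y
    locmax <- which(diff(sign(diff(y))) == -2) + 1
    if (length(locmax) == 0) locmax <- which.max(y)
    pk <- dn$x[locmax][order(y[locmax], decreasing = TRUE)]
    out[[r]] <- list(n_pairs = length(v), density = dn, peaks = pk)
  }
  out
}
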