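# per-group per-locus allele and genotype counts from dosages
group_locus_counts <- function(g, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(g$dosages))
  x <- g$dosages
  groups <- sort(unique(labels))
  lapply(stats::setNames(groups, groups), function(gr) {
    xs <- x[labels == gr, , drop = FALSE]
    n_geno <- colSums(!is.na(xs))
    alt <- colSums(xs, na.rm = TRUE)
    het <- colSums(xs == 1L, na.rm = TRUE)
    list(n_geno = n_geno,          # non-missing genotypes per locus
         n_alleles = 2 * n_geno,   # non-missing alleles per locus
         alt = alt,                # ALT allele count
         het = het)                # heterozygote count
  })
}

#' Per-group diversity statistics
#'
#' Per locus and group: nucleotide diversity
#' `pi = 1 - sum_a choose(n_a, 2) / choose(n, 2)` over allele counts
#' (unbiased combinatorial estimator), observed heterozygosity `H_O` (fraction
#' of heterozygous calls), expected heterozygosity `H_E = 1 - sum p^2`.
#' Group values are means across loci weighted by the non-missing allele
#' count, and `F_IS = 1 - sum(w H_O) / sum(w H_E)` as a ratio of weighted
#' sums (robust to monomorphic loci).
#'
#' @param g a [genotype_matrix].
#' @param labels per-accession group labels (groups of size < 2 are skipped
#'   with a warning).
#' @return data.frame with one row per group: `group`, `n`, `pi`, `h_obs`,
#'   `h_exp`, `f_is`.
#' @export
per_group_diversity <- function(g, labels) {
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) of size < 2 skipped: ", paste(small, collapse = ", "))
  }
  cnt <- group_locus_counts(g, labels)
  cnt <- cnt[setdiff(names(cnt), small)]
  out <- lapply(names(cnt), function(gr) {
    cc <- cnt[[gr]]
    n <- cc$n_alleles
    use <- n >= 2
    n <- n[use]; alt <- cc$alt[use]; ref <- n - alt
    het <- cc$het[use]; ng <- cc$n_geno[use]
    pi_l <- 1 - (choose(alt, 2) + choose(ref, 2)) / choose(n, 2)
    p <- alt / n
    he_l <- 1 - (p^2 + (1 - p)^2)
    ho_l <- het / ng
    w <- n
    sw <- sum(w)
    he_w <- sum(w * he_l)
    data.frame(group = gr, n = sum(labels == gr),
               pi = sum(w * pi_l) / sw,
               h_obs = sum(w * ho_l) / sw,
               h_exp = he_w / sw,
               f_is = if (he_w > 0) 1 - sum(w * ho_l) / he_w else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rarefied allelic richness per group (Hurlbert)
#'
#' Per locus and group, the expected number of distinct alleles in a random
#' subsample of `g_r` alleles:
#' `sum_a (1 - choose(N - N_a, g_r) / choose(N, g_r))`.  The group richness is
#' the mean over loci.  `rarefaction_size = NULL` uses the largest size every
#' group supports at every locus (the minimum per-locus non-missing allele
#' count across groups).
#'
#' @param g a [genotype_matrix].
#' @param labels per-accession group labels.
#' @param rarefaction_size number of alleles to rarefy to (>= 2), or NULL for
#'   the automatic minimum.
#' @return data.frame with columns `group`, `richness`, and the
#'   `rarefaction_size` used as an attribute.
#' @export
allelic_richness <- function(g, labels, rarefaction_size = NULL) {
  cnt <- group_locus_counts(g, labels)
  if (is.null(rarefaction_size)) {
    rarefaction_size <- min(vapply(cnt, function(cc) min(cc$n_alleles), 0))
  }
  g_r <- rarefaction_size
  if (g_r < 2) stop("rarefaction size must be >= 2", call. = FALSE)
  bad <- vapply(cnt, function(cc) any(cc$n_alleles < g_r), TRUE)
  if (any(bad)) {
    stop("rarefaction size exceeds observed allele counts in group(s): ",
         paste(names(cnt)[bad], collapse = ", "), call. = FALSE)
  }
  rich <- vapply(cnt, function(cc) {
    N <- cc$n_alleles; alt <- cc$alt; ref <- N - alt
    term <- function(na) {
      # 1 - C(N - na, g_r)/C(N, g_r), zero contribution for absent alleles
      out <- 1 - exp(lchoose(N - na, g_r) - lchoose(N, g_r))
      out[na == 0] <- 0
      out
    }
    mean(term(alt) + term(ref))
  }, 0)
  out <- data.frame(group = names(cnt), richness = unname(rich),
                    stringsAsFactors = FALSE)
  attr(out, "rarefaction_size") <- g_r
  out
}

#' Private allele counts per group
#'
#' Counts (locus, allele) combinations observed in exactly one group.
#'
#' @param g a [genotype_matrix].
#' @param labels per-accession group labels.
#' @return data.frame with columns `group`, `private_alleles`.
#' @export
private_alleles <- function(g, labels) {
  cnt <- group_locus_counts(g, labels)
  groups <- names(cnt)
  has_alt <- vapply(cnt, function(cc) cc$alt > 0, logical(ncol(g$dosages)))
  has_ref <- vapply(cnt, function(cc) (cc$n_alleles - cc$alt) > 0,
                    logical(ncol(g$dosages)))
  if (is.null(dim(has_alt))) {   # single-locus panel
    has_alt <- matrix(has_alt, nrow = 1)
    has_ref <- matrix(has_ref, nrow = 1)
  }
  priv <- function(mat) {
    one <- rowSums(mat) == 1
    colSums(mat & one)
  }
  data.frame(group = groups,
             private_alleles = as.integer(priv(has_alt) + priv(has_ref)),
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for one
# biallelic locus across r groups.  n_i = genotype counts, p_i = ALT
# frequencies, h_i = observed heterozygote proportions.
wc_components <- function(n_i, p_i, h_i) {
  use <- n_i > 0
  n_i <- n_i[use]; p_i <- p_i[use]; h_i <- h_i[use]
  r <- length(n_i)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham F_ST between groups
#'
#' Multi-locus estimates as the ratio of sums of the per-locus variance
#' components, `sum(a) / sum(a + b + c)`; negative per-locus components are
#' retained before summation and slightly negative estimates are not
#' truncated.
#'
#' @param g a [genotype_matrix].
#' @param labels per-accession group labels; groups with fewer than 2 members
#'   are dropped.
#' @return symmetric matrix of F_ST estimates (diagonal 0; `NA` where a pair
#'   shares no informative loci).
#' @export
pairwise_fst <- function(g, labels) {
  labels <- as.character(labels)
  sizes <- table(labels)
  groups <- names(sizes)[sizes >= 2]
  cnt <- group_locus_counts(g, labels)[groups]
  out <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
  diag(out) <- 0
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    c1 <- cnt[[groups[i]]]; c2 <- cnt[[groups[j]]]
    sa <- 0; sabc <- 0; any_l <- FALSE
    for (l in seq_len(ncol(g$dosages))) {
      n_i <- c(c1$n_geno[l], c2$n_geno[l])
      if (any(n_i == 0)) next
      p_i <- c(c1$alt[l], c2$alt[l]) / (2 * n_i)
      h_i <- c(c1$het[l], c2$het[l]) / n_i
      comp <- wc_components(n_i, p_i, h_i)
      if (anyNA(comp)) next
      sa <- sa + comp["a"]; sabc <- sabc + sum(comp)
      any_l <- TRUE
    }
    out[i, j] <- out[j, i] <- if (any_l && sabc != 0) sa / sabc else NA_real_
  }
  out
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared Euclidean distances between dosage vectors into among-
#' and within-group components (Excoffier-style expected mean squares with
#' group-size weighting), with a permutation p-value for Phi_ST under random
#' label reassignment.
#'
#' @param g a [genotype_matrix] with complete dosages.
#' @param labels per-accession group labels; groups of size 1 are excluded
#'   with a warning.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return an object of class `amova_result`: data.frame `table` (df, SS, MS
#'   per stratum), `variance_components`, `variance_pct` (negative components
#'   truncated to zero for percentages), `phi_st`, `p_value`, `n_perm`.
#' @export
amova <- function(g, labels, n_perm = 999, seed = 1L) {
  labels <- as.character(labels)
  if (anyNA(g$dosages)) stop("complete (imputed) dosages required", call. = FALSE)
  sizes <- table(labels)
  drop <- names(sizes)[sizes < 2]
  if (length(drop)) {
    warning("group(s) of size 1 excluded: ", paste(drop, collapse = ", "))
    keep <- !(labels %in% drop)
    g <- subset_genotypes(g, samples = keep)
    labels <- labels[keep]
  }
  groups <- unique(labels)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  x <- g$dosages
  storage.mode(x) <- "double"
  n <- nrow(x)
  # squared Euclidean distances via the Gram matrix
  gram <- tcrossprod(x)
  sq <- diag(gram)
  d2 <- outer(sq, sq, `+`) - 2 * gram
  d2[d2 < 0] <- 0

  ssd_within_of <- function(lab) {
    s <- 0
    for (gr in unique(lab)) {
      idx <- which(lab == gr)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_total <- sum(d2) / (2 * n)
  ss_within <- ssd_within_of(labels)
  ss_among <- ss_total - ss_within
  k <- length(groups)
  df_among <- k - 1
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_g <- as.numeric(table(labels))
  n0 <- (n - sum(n_g^2) / n) / (k - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  phi <- sigma_among / (sigma_among + sigma_within)

  rng <- local_rng(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    lab_p <- labels[rng$sample_int(n, n)]
    ssw <- ssd_within_of(lab_p)
    msa_p <- (ss_total - ssw) / df_among
    msw_p <- ssw / df_within
    sa_p <- (msa_p - msw_p) / n0
    phi_p <- sa_p / (sa_p + msw_p)
    if (phi_p >= phi) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (n_perm + 1)

  comp <- c(among = sigma_among, within = sigma_within)
  comp_trunc <- pmax(comp, 0)
  pct <- 100 * comp_trunc / sum(comp_trunc)
  tab <- data.frame(
    stratum = c("among groups", "within groups", "total"),
    df = c(df_among, df_within, n - 1),
    SS = c(ss_among, ss_within, ss_total),
    MS = c(ms_among, ms_within, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 variance_components = comp,
                 variance_pct = pct,
                 phi_st = phi,
                 p_value = p,
                 n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (one level)\n")
  print(x$table, digits = 6, row.names = FALSE)
  cat(sprintf("  variance %%: among %.2f, within %.2f;  Phi_ST = %.4f, p = %.4g (%d permutations)\n",
              x$variance_pct["among"], x$variance_pct["within"],
              x$phi_st, x$p_value, x$n_perm))
  invisible(x)
}
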