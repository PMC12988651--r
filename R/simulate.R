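#' Configuration for the synthetic SNP panel generator
#'
#' The generator emulates a highly selfing crop genotyped at a few thousand
#' biallelic SNPs: ancestral populations diverged under a Balding-Nichols
#' model, Dirichlet admixture, strong excess homozygosity, planted
#' exact/near-duplicate accessions with shared passport aliases, planted
#' parent-offspring pairs, missing data, and collection/region labels
#' correlated with ancestry.
#'
#' @param n_populations number of ancestral populations (K).
#' @param n_per_population accessions drawn per population.
#' @param n_markers number of biallelic SNP markers.
#' @param divergence_f Balding-Nichols drift parameter in (0,1); population
#'   allele frequencies are Beta(p(1-f)/f, (1-p)(1-f)/f) around the ancestral
#'   frequency p.
#' @param selfing_fis target inbreeding coefficient in [0,1); genotypes are
#'   drawn with this excess-homozygosity F.
#' @param admixture_alpha Dirichlet concentration for per-accession admixture
#'   proportions (small values give near-pure accessions).
#' @param duplicate_rate fraction of base accessions duplicated (planted
#'   duplicates), in [0,1).
#' @param duplicate_error_rate per-genotype probability that a copied call is
#'   perturbed (symmetric one-allele flip).
#' @param alias_share_prob probability a planted duplicate carries the source
#'   accession's name as an alias.
#' @param parent_offspring_pairs number of planted parent-offspring pairs.
#' @param missing_rate per-call missingness probability, in [0,1).
#' @param maf_floor minimum ancestral allele frequency; ancestral frequencies
#'   are Uniform(maf_floor, 1 - maf_floor).
#' @param seed integer RNG seed; output is reproducible given the seed.
#' @param collections character vector of collection labels.
#' @param regions character vector of region labels (recycled over
#'   populations).
#' @param label_leakage probability an accession's region label is drawn
#'   uniformly instead of from its majority population's region, controlling
#'   how sharp the planted geographic signal is.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_populations = 3,
                              n_per_population = 100,
                              n_markers = 2000,
                              divergence_f = 0.3,
                              selfing_fis = 0.85,
                              admixture_alpha = 0.2,
                              duplicate_rate = 0.10,
                              duplicate_error_rate = 0.005,
                              alias_share_prob = 0.8,
                              parent_offspring_pairs = 10,
                              missing_rate = 0.05,
                              maf_floor = 0.05,
                              seed = 1L,
                              collections = c("AGG", "IITA", "USDA", "NARO"),
                              regions = c("Africa", "Asia", "Europe",
                                          "North America", "South America"),
                              label_leakage = 0.1) {
  cfg <- list(n_populations = n_populations,
              n_per_population = n_per_population,
              n_markers = n_markers,
              divergence_f = divergence_f,
              selfing_fis = selfing_fis,
              admixture_alpha = admixture_alpha,
              duplicate_rate = duplicate_rate,
              duplicate_error_rate = duplicate_error_rate,
              alias_share_prob = alias_share_prob,
              parent_offspring_pairs = parent_offspring_pairs,
              missing_rate = missing_rate,
              maf_floor = maf_floor,
              seed = as.integer(seed),
              collections = collections,
              regions = regions,
              label_leakage = label_leakage)
  stopifnot(n_populations >= 1, n_per_population >= 1, n_markers >= 1,
            divergence_f > 0, divergence_f < 1,
            selfing_fis >= 0, selfing_fis < 1,
            admixture_alpha > 0,
            duplicate_rate >= 0, duplicate_rate < 1,
            duplicate_error_rate >= 0, duplicate_error_rate <= 1,
            alias_share_prob >= 0, alias_share_prob <= 1,
            parent_offspring_pairs >= 0,
            missing_rate >= 0, missing_rate < 1,
            maf_floor > 0, maf_floor < 0.5,
            label_leakage >= 0, label_leakage <= 1)
  structure(cfg, class = "simulation_config")
}

#' Simulate a genotype panel with planted truth
#'
#' Draws ancestral allele frequencies Uniform(`maf_floor`, 1 - `maf_floor`),
#' population frequencies from a Balding-Nichols Beta around them, admixture
#' proportions Dirichlet(`admixture_alpha`), and genotypes with excess
#' homozygosity F = `selfing_fis` from each accession's admixed frequency.
#' Planted duplicates copy a base accession's genotype with independent
#' per-site copy errors; parent-offspring offspring inherit one allele from
#' the parent and one from the parent's majority population.  Passport labels
#' (collection, region) track the majority population with configurable
#' leakage.
#'
#' @param config a [simulation_config].
#' @return list with elements `genotypes` (a [genotype_matrix]), `passport`
#'   (data.frame) and `truth` (list: `duplicate_pairs`, `relative_pairs`,
#'   `true_q`, `true_population`).
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  K <- cf$n_populations
  L <- cf$n_markers
  n_base <- K * cf$n_per_population

  # ancestral and population allele frequencies (Balding-Nichols)
  p_anc <- stats::runif(L, cf$maf_floor, 1 - cf$maf_floor)
  f <- cf$divergence_f
  p_pop <- matrix(0, K, L)
  for (k in seq_len(K)) {
    p_pop[k, ] <- stats::rbeta(L, p_anc * (1 - f) / f,
                               (1 - p_anc) * (1 - f) / f)
  }

  # admixture proportions ~ symmetric Dirichlet(alpha); the true population
  # label is the majority-ancestry component (small alpha => near-pure rows)
  q <- matrix(stats::rgamma(n_base * K, shape = cf$admixture_alpha), n_base, K)
  # tiny alpha can underflow every component; the Dirichlet limit as
  # alpha -> 0 is a uniformly random vertex
  zero <- rowSums(q) == 0
  if (any(zero)) {
    q[zero, ] <- 0
    q[cbind(which(zero), sample.int(K, sum(zero), replace = TRUE))] <- 1
  }
  q <- q / rowSums(q)
  true_pop <- max.col(q, ties.method = "first")

  # genotypes with excess homozygosity from admixed frequencies
  pi_il <- q %*% p_pop                      # accession x marker ALT freq
  dos <- draw_inbred_genotypes(pi_il, cf$selfing_fis)

  ids <- sprintf("ACC%04d", seq_len(n_base))
  names_ <- sprintf("LINE-%04d", seq_len(n_base))

  # planted parent-offspring pairs (offspring appended; outbred union of a
  # transmitted parental allele and a population allele)
  rel_pairs <- data.frame(id1 = character(0), id2 = character(0),
                          relationship = character(0))
  n_po <- cf$parent_offspring_pairs
  if (n_po > 0) {
    if (n_po > n_base) stop("more parent-offspring pairs than accessions")
    parents <- sample.int(n_base, n_po)
    off <- matrix(NA_integer_, n_po, L)
    for (i in seq_len(n_po)) {
      pg <- dos[parents[i], ]
      transmitted <- ifelse(pg == 0L, 0L,
                            ifelse(pg == 2L, 1L,
                                   stats::rbinom(L, 1, 0.5)))
      k <- true_pop[parents[i]]
      other <- stats::rbinom(L, 1, p_pop[k, ])
      off[i, ] <- as.integer(transmitted + other)
    }
    off_ids <- sprintf("OFF%04d", seq_len(n_po))
    dos <- rbind(dos, off)
    ids <- c(ids, off_ids)
    names_ <- c(names_, sprintf("LINE-OFF-%04d", seq_len(n_po)))
    true_pop <- c(true_pop, true_pop[parents])
    q <- rbind(q, q[parents, , drop = FALSE])
    rel_pairs <- data.frame(id1 = sprintf("ACC%04d", parents),
                            id2 = off_ids,
                            relationship = "parent-offspring")
  }

  # planted duplicates: copy a base genotype, flip one allele per errored call
  n_dup <- round(cf$duplicate_rate * n_base)
  dup_pairs <- data.frame(id1 = character(0), id2 = character(0))
  alias <- rep("", length(ids))
  if (n_dup > 0) {
    if (n_dup > n_base) stop("duplicate_rate implies more duplicates than accessions")
    src <- sample.int(n_base, n_dup)
    dup <- dos[src, , drop = FALSE]
    err <- matrix(stats::runif(n_dup * L) < cf$duplicate_error_rate, n_dup, L)
    if (any(err)) {
      cur <- dup[err]
      up <- stats::rbinom(sum(err), 1, 0.5) == 1
      nw <- ifelse(cur == 0L, 1L, ifelse(cur == 2L, 1L, ifelse(up, 2L, 0L)))
      dup[err] <- as.integer(nw)
    }
    dup_ids <- sprintf("DUP%04d", seq_len(n_dup))
    shared <- stats::runif(n_dup) < cf$alias_share_prob
    dup_names <- sprintf("LINE-DUP-%04d", seq_len(n_dup))
    dup_alias <- ifelse(shared, names_[src], "")
    dos <- rbind(dos, dup)
    ids <- c(ids, dup_ids)
    names_ <- c(names_, dup_names)
    alias <- c(alias, dup_alias)
    true_pop <- c(true_pop, true_pop[src])
    q <- rbind(q, q[src, , drop = FALSE])
    dup_pairs <- data.frame(id1 = sprintf("ACC%04d", src), id2 = dup_ids)
  } else {
    alias <- rep("", length(ids))
  }

  # missingness
  n_all <- nrow(dos)
  if (cf$missing_rate > 0) {
    miss <- matrix(stats::runif(n_all * L) < cf$missing_rate, n_all, L)
    dos[miss] <- NA_integer_
  }

  # marker map: 11 chromosomes, positions spaced deterministically
  n_chr <- min(11L, L)
  chrom <- sort(rep_len(sprintf("Vu%02d", seq_len(n_chr)), L))
  pos <- unlist(lapply(table(chrom), function(m) seq_len(m) * 1000L),
                use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  refs <- sample(alleles, L, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(alleles, r), 1), "")
  markers <- data.frame(chrom = chrom, pos = pos, ref = refs, alt = alts,
                        stringsAsFactors = FALSE)

  geno <- genotype_matrix(dos, markers, accession_ids = ids)

  # passport: region tracks majority population with leakage
  region_of_pop <- rep_len(cf$regions, K)
  leak <- stats::runif(n_all) < cf$label_leakage
  region <- ifelse(leak, sample(cf$regions, n_all, replace = TRUE),
                   region_of_pop[true_pop])
  collection <- sample(cf$collections, n_all, replace = TRUE)
  passport <- data.frame(
    accession_id = ids,
    name = names_,
    aliases = alias,
    collection = collection,
    country = region,
    region = region,
    improvement_status = sample(c("Landrace", "Breeding Line",
                                  "Advanced Cultivar", "Unknown"),
                                n_all, replace = TRUE,
                                prob = c(0.5, 0.2, 0.1, 0.2)),
    cultivar_group = sample(c("unguiculata", "sesquipedalis", "biflora"),
                            n_all, replace = TRUE, prob = c(0.9, 0.07, 0.03)),
    stringsAsFactors = FALSE
  )

  truth <- list(duplicate_pairs = dup_pairs,
                relative_pairs = rel_pairs,
                true_q = q,
                true_population = stats::setNames(true_pop, ids))
  list(genotypes = geno, passport = passport, truth = truth)
}

# Genotype draw with excess homozygosity: given per-entry ALT frequency pi
# and inbreeding F, P(2) = pi^2 + F pi (1-pi), P(1) = 2 pi (1-pi) (1-F),
# P(0) = (1-pi)^2 + F pi (1-pi).
draw_inbred_genotypes <- function(pi_il, fis) {
  p2 <- pi_il^2 + fis * pi_il * (1 - pi_il)
  p1 <- 2 * pi_il * (1 - pi_il) * (1 - fis)
  u <- stats::runif(length(pi_il))
  out <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
  matrix(as.integer(out), nrow(pi_il), ncol(pi_il))
}

#' Export a simulated panel as plain-text fixtures
#'
#' Writes the genotypes as VCF, the passport table as CSV and the truth
#' tables as TSV (`truth_pairs.tsv` with planted duplicate/relative pairs,
#' `truth_q.tsv` with true admixture proportions and population labels).
#' Round-trips losslessly through [read_vcf()] / [read_passport()].
#'
#' @param panel result of [simulate_panel()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
export_fixture <- function(panel, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- c(vcf = file.path(out_dir, "panel.vcf"),
             passport = file.path(out_dir, "passport.csv"),
             pairs = file.path(out_dir, "truth_pairs.tsv"),
             q = file.path(out_dir, "truth_q.tsv"))
  write_vcf(panel$genotypes, paths["vcf"])
  write_passport(panel$passport, paths["passport"])
  tr <- panel$truth
  pairs <- rbind(
    if (nrow(tr$duplicate_pairs))
      cbind(tr$duplicate_pairs, relationship = "duplicate") else NULL,
    tr$relative_pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(id1 = character(0), id2 = character(0),
                        relationship = character(0))
  }
  utils::write.table(pairs, paths["pairs"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  qdf <- data.frame(accession_id = names(tr$true_population),
                    true_population = unname(tr$true_population),
                    tr$true_q, check.names = FALSE)
  names(qdf)[-(1:2)] <- paste0("Q", seq_len(ncol(tr$true_q)))
  utils::write.table(qdf, paths["q"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
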