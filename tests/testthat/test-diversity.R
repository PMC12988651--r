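test_that("per-locus diversity matches direct count arithmetic", {
  # n = 2 accessions with genotypes {0, 2}: allele counts (2, 2),
  # pi = 1 - (C(2,2) + C(2,2))/C(4,2) = 2/3
  g <- toy_geno(rbind(c(0L), c(2L)))
  dv <- per_group_diversity(g, c("g", "g"))
  expect_equal(dv$pi, 2 / 3, tolerance = 1e-12)
  expect_equal(dv$h_obs, 0)
  expect_equal(dv$h_exp, 0.5)
  expect_equal(dv$f_is, 1)

  # all-homozygous group split 50/50: H_O = 0, F_IS = 1
  g2 <- toy_geno(matrix(rep(c(0L, 2L), each = 5), 10, 4))
  dv2 <- per_group_diversity(g2, rep("g", 10))
  expect_equal(dv2$h_obs, 0)
  expect_equal(dv2$f_is, 1)

  # monomorphic locus contributes zero diversity
  g3 <- toy_geno(matrix(0L, 6, 3))
  dv3 <- per_group_diversity(g3, rep("g", 6))
  expect_equal(dv3$pi, 0)
  expect_equal(dv3$h_exp, 0)
})

test_that("diversity statistics stay in their bounds on noisy panels", {
  cfg <- simulation_config(n_populations = 3, n_per_population = 30,
                           n_markers = 300, missing_rate = 0.1, seed = 41)
  sim <- simulate_panel(cfg)
  lab <- sim$truth$true_population
  dv <- per_group_diversity(sim$genotypes, lab)
  expect_true(all(dv$pi >= 0 & dv$pi <= 1))
  expect_true(all(dv$h_obs >= 0 & dv$h_obs <= 1))
  expect_true(all(dv$h_exp >= 0 & dv$h_exp <= 1))
  expect_true(all(dv$f_is >= -1 & dv$f_is <= 1))
  rich <- allelic_richness(sim$genotypes, lab)
  expect_true(all(rich$richness >= 1 & rich$richness <= 2))
})

test_that("Hurlbert richness matches the combinatorial example and rarefaction laws", {
  # allele counts (3, 1) rarefied to 2: (1 - 0) + (1 - C(3,2)/C(4,2)) = 1.5
  g <- toy_geno(rbind(c(1L), c(0L)))
  r <- allelic_richness(g, c("g", "g"), rarefaction_size = 2)
  expect_equal(r$richness, 1.5, tolerance = 1e-12)
  # brute force: all C(4,2) = 6 subsets of 2 alleles from {T,A,A,A}
  pool <- c(1, 0, 0, 0)
  subsets <- combn(4, 2)
  expect_equal(mean(apply(subsets, 2, function(s) length(unique(pool[s])))),
               1.5)
  # monomorphic locus has richness 1 at any size
  gm <- toy_geno(matrix(2L, 4, 2))
  expect_equal(allelic_richness(gm, rep("g", 4), 2)$richness, 1)
  expect_equal(allelic_richness(gm, rep("g", 4), 6)$richness, 1)
  # richness is non-decreasing in the rarefaction size
  set.seed(42)
  gx <- toy_geno(matrix(sample(0:2, 10 * 20, TRUE), 10, 20))
  sizes <- c(2, 6, 12, 20)
  vals <- vapply(sizes, function(s)
    allelic_richness(gx, rep("g", 10), s)$richness, 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("private alleles are counted only where exclusive to one group", {
  # group A fixed ALT at locus 1 (ALT absent in B): ALT@1 private to A,
  # REF@1 private to B; locus 2 shared in both groups
  d <- rbind(c(2L, 1L), c(2L, 0L), c(0L, 1L), c(0L, 0L))
  g <- toy_geno(d)
  pa <- private_alleles(g, c("A", "A", "B", "B"))
  expect_equal(pa$private_alleles[pa$group == "A"], 1L)
  expect_equal(pa$private_alleles[pa$group == "B"], 1L)
  expect_lte(sum(pa$private_alleles), 2 * ncol(d))
})

test_that("Weir-Cockerham F_ST matches the limits and the brute-force oracle", {
  gf <- toy_geno(rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L)))
  expect_equal(pairwise_fst(gf, c("p1", "p1", "p2", "p2"))["p1", "p2"], 1)

  set.seed(43)
  d <- matrix(sample(0:2, 4 * 3, replace = TRUE, prob = c(.5, .2, .3)), 4, 3)
  g <- toy_geno(d)
  lab <- c("x", "x", "y", "y")
  expect_equal(pairwise_fst(g, lab)["x", "y"], fst_oracle(g, lab),
               tolerance = 1e-12)

  # random halves of one population: near zero, possibly negative, untruncated
  vals <- c()
  for (s in 1:5) {
    cfg <- simulation_config(n_populations = 1, n_per_population = 100,
                             n_markers = 1000, divergence_f = 0.05,
                             admixture_alpha = 1, duplicate_rate = 0,
                             parent_offspring_pairs = 0, missing_rate = 0,
                             seed = 50 + s)
    sim <- simulate_panel(cfg)
    lab <- rep(c("h1", "h2"), 50)
    vals <- c(vals, pairwise_fst(sim$genotypes, lab)["h1", "h2"])
  }
  expect_true(all(abs(vals) < 0.02))
  expect_true(any(vals < 0))   # negative estimates are reported as computed
})

test_that("AMOVA attributes all variance among groups in the fixed-difference limit", {
  g <- toy_geno(cbind(c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L)))
  am <- amova(g, c("p1", "p1", "p2", "p2"), n_perm = 99, seed = 1)
  expect_equal(unname(am$variance_pct["among"]), 100)
  expect_equal(sum(am$variance_pct), 100, tolerance = 0.01)
  expect_equal(am$table$df[1] + am$table$df[2], 4 - 1)
  expect_equal(am$table$SS[3], am$table$SS[1] + am$table$SS[2],
               tolerance = 1e-9)
})

test_that("AMOVA sums of squares agree with the distance-based partition in vegan", {
  skip_if_not_installed("vegan")
  cfg <- simulation_config(n_populations = 2, n_per_population = 15,
                           n_markers = 100, divergence_f = 0.2,
                           duplicate_rate = 0, parent_offspring_pairs = 0,
                           missing_rate = 0, seed = 44)
  sim <- simulate_panel(cfg)
  lab <- factor(sim$truth$true_population)
  am <- amova(sim$genotypes, lab, n_perm = 9, seed = 1)
  dd <- dist(sim$genotypes$dosages)
  ad <- vegan::adonis2(dd ~ lab, permutations = 2)
  expect_equal(am$table$SS[1], ad$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(am$table$SS[2], ad$SumOfSqs[2], tolerance = 1e-8)
})

test_that("AMOVA is calibrated: null labels give small among-variance, strong structure the minimal p", {
  # null: random labels on one population
  ps <- pcts <- c()
  for (s in 1:5) {
    cfg <- simulation_config(n_populations = 1, n_per_population = 60,
                             n_markers = 300, divergence_f = 0.05,
                             admixture_alpha = 1, duplicate_rate = 0,
                             parent_offspring_pairs = 0, missing_rate = 0,
                             seed = 60 + s)
    sim <- simulate_panel(cfg)
    lab <- rep(c("a", "b"), 30)
    am <- amova(sim$genotypes, lab, n_perm = 99, seed = s)
    ps <- c(ps, am$p_value); pcts <- c(pcts, am$variance_pct["among"])
  }
  expect_gte(mean(ps > 0.05), 0.8)
  expect_true(all(pcts < 5))
  # strong divergence: p hits the permutation floor
  cfg <- simulation_config(n_populations = 2, n_per_population = 40,
                           n_markers = 500, divergence_f = 0.3,
                           admixture_alpha = 0.01, duplicate_rate = 0,
                           parent_offspring_pairs = 0, missing_rate = 0,
                           seed = 66)
  sim <- simulate_panel(cfg)
  am <- amova(sim$genotypes, sim$truth$true_population, n_perm = 999, seed = 2)
  expect_equal(am$p_value, 0.001)
})
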