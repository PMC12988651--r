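make_vcf <- function(lines, samples = c("S1", "S2", "S3", "S4")) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines), f)
  f
}

test_that("GT calls parse to dosages, with phase ignored and '.' as missing", {
  f <- make_vcf(paste(c("1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT",
                        "0/0", "0|1", "1/1", "./."), collapse = "\t"))
  g <- read_vcf(f)
  expect_identical(unname(g$dosages[, 1]), c(0L, 1L, 2L, NA))
  expect_identical(g$accession_ids, c("S1", "S2", "S3", "S4"))
})

test_that("multi-allelic records are rejected", {
  f <- make_vcf(paste(c("1", "100", "snp1", "A", "T,G", ".", "PASS", ".", "GT",
                        "0/0", "0/1", "1/1", "2/2"), collapse = "\t"))
  expect_error(read_vcf(f), "multi-allelic")
})

test_that("QC boundaries are inclusive exactly as declared", {
  # marker with call rate exactly 0.80 (8/10 calls) must be removed
  set.seed(1)
  d <- matrix(sample(0:1, 10 * 5, replace = TRUE), 10, 5)
  d[1:2, 3] <- NA            # marker 3: call rate 0.8
  g <- toy_geno(d)
  res <- apply_qc_filters(g, marker_het_min_excl = 1.1, sample_het_min_excl = 1.1)
  expect_equal(ncol(res$genotypes$dosages), 4)
  expect_equal(res$report$steps$marker_call_rate$marker, 3)

  # sample heterozygosity 0.19 retained, 0.20 removed
  d <- matrix(0L, 3, 100)
  d[2, 1:19] <- 1L            # het 0.19
  d[3, 1:20] <- 1L            # het 0.20
  g <- toy_geno(d, ids = c("low", "mid", "high"))
  res <- apply_qc_filters(g, marker_het_min_excl = 1.1)
  expect_identical(res$genotypes$accession_ids, c("low", "mid"))
})

test_that("clean panels pass QC unchanged with an empty report", {
  d <- matrix(rep(c(0L, 2L), 50), 10, 10)
  g <- toy_geno(d)
  res <- apply_qc_filters(g)
  expect_identical(res$genotypes$dosages, g$dosages)
  expect_equal(nrow(res$report$steps$sample_call_rate), 0)
  expect_equal(nrow(res$report$steps$marker_call_rate), 0)
  expect_equal(nrow(res$report$steps$marker_het), 0)
  expect_equal(nrow(res$report$steps$sample_het), 0)
})

test_that("QC report counts reconcile at every step", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 40,
                           n_markers = 300, missing_rate = 0.25,
                           selfing_fis = 0.3, seed = 8)
  sim <- simulate_panel(cfg)
  res <- apply_qc_filters(sim$genotypes, impute_seed = 9)
  rp <- res$report
  expect_equal(rp$n_samples_in - nrow(rp$steps$sample_call_rate) -
                 nrow(rp$steps$sample_het), rp$n_samples_out)
  expect_equal(rp$n_markers_in - nrow(rp$steps$marker_call_rate) -
                 nrow(rp$steps$marker_het), rp$n_markers_out)
  expect_false(anyNA(res$genotypes$dosages))   # imputed between steps
})

test_that("imputation fills only missing calls, deterministically", {
  set.seed(3)
  d <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  d[sample(200, 40)] <- NA
  g <- toy_geno(d)
  a <- impute_missing(g, seed = 4)
  b <- impute_missing(g, seed = 4)
  expect_identical(a$dosages, b$dosages)
  expect_false(anyNA(a$dosages))
  was <- !is.na(d)
  expect_identical(a$dosages[was], d[was])
  # all-reference marker imputes to reference
  d2 <- matrix(0L, 10, 2); d2[3, 1] <- NA
  a2 <- impute_missing(toy_geno(d2), seed = 1)
  expect_equal(unname(a2$dosages[3, 1]), 0L)
  # no missing data: identity
  expect_identical(impute_missing(toy_geno(matrix(1L, 4, 3)), 1)$dosages,
                   toy_geno(matrix(1L, 4, 3))$dosages)
})

test_that("MAF filtering keeps the boundary and drops monomorphic markers", {
  d <- cbind(rep(0L, 100),                 # monomorphic, MAF 0
             c(1L, rep(0L, 99)),           # MAF 0.005
             c(1L, 1L, rep(0L, 98)),       # MAF exactly 0.01
             rep(1L, 100))                 # MAF 0.5
  g <- toy_geno(d)
  out <- filter_maf(g, 0.01)
  expect_equal(ncol(out$dosages), 2)
  expect_identical(out$markers$pos, c(3L, 4L))
  all5 <- toy_geno(matrix(rep(c(0L, 2L), 50), 100, 4))
  expect_equal(ncol(filter_maf(all5, 0.01)$dosages), 4)
})

test_that("LD pruning removes duplicated columns and spares independent markers", {
  set.seed(5)
  x <- matrix(rbinom(80 * 40, 2, 0.4), 80, 40)
  x[, 7] <- x[, 6]
  g <- toy_geno(x)
  out <- ld_prune(g)
  kept <- out$markers$pos
  expect_equal(sum(c(6, 7) %in% kept), 1)
  # independent markers survive
  set.seed(6)
  gi <- toy_geno(matrix(rbinom(200 * 500, 2, 0.5), 200, 500))
  expect_equal(ncol(ld_prune(gi)$dosages), 500)
})

test_that("LD pruning matches the brute-force reference on a 60-marker toy", {
  set.seed(7)
  base <- matrix(rbinom(60 * 60, 2, 0.45), 60, 60)
  # plant correlated clusters
  for (j in c(5, 12, 33, 48)) {
    base[, j + 1] <- base[, j]
    flip <- sample(60, 6)
    base[flip, j + 1] <- sample(0:2, 6, replace = TRUE)
  }
  g <- genotype_matrix(base, data.frame(
    chrom = rep(c("1", "2"), each = 30), pos = rep(1:30, 2),
    ref = "A", alt = "T"))
  out <- ld_prune(g, window = 10, step = 3, r2_max = 0.5)
  expect_identical(which(paste(g$markers$chrom, g$markers$pos) %in%
                           paste(out$markers$chrom, out$markers$pos)),
                   ld_prune_oracle(g, window = 10, step = 3, r2_max = 0.5))
})

test_that("PCA separates diverged populations and respects SVD structure", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 40,
                           n_markers = 500, divergence_f = 0.3,
                           admixture_alpha = 0.01, duplicate_rate = 0,
                           parent_offspring_pairs = 0, missing_rate = 0,
                           seed = 9)
  sim <- simulate_panel(cfg)
  pc <- pca_genotypes(sim$genotypes, 5)
  pop <- sim$truth$true_population
  s1 <- pc$scores[pop == 1, 1]; s2 <- pc$scores[pop == 2, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # no overlap on PC1
  expect_true(all(diff(pc$sdev) <= 1e-12))             # non-increasing variance
  expect_lte(sum(pc$explained), 1)
  # identical accessions get identical scores
  d <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L))
  expect_warning(pc2 <- pca_genotypes(toy_geno(d), 2), "rank")
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
})
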