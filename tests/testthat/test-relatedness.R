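test_that("Nei distance matches hand computation and the naive oracle", {
  # A hom-ref at 2 loci, B het at locus 1: I = 0.75/sqrt(0.75), D ~ 0.1438
  g <- toy_geno(rbind(A = c(0L, 0L), B = c(1L, 0L)), ids = c("A", "B"))
  d <- nei_distance(g)
  expect_equal(d["A", "B"], -log(0.75 / sqrt(0.75)), tolerance = 1e-12)
  expect_equal(d["A", "B"], 0.1438, tolerance = 1e-3)
  expect_equal(d["A", "A"], 0)

  set.seed(11)
  x <- matrix(sample(c(0:2, NA), 8 * 30, replace = TRUE,
                     prob = c(.4, .2, .3, .1)), 8, 30)
  g <- toy_geno(x, ids = letters[1:8])
  d <- nei_distance(g)
  expect_true(isSymmetric(d))
  for (pair in list(c(1, 2), c(3, 7), c(4, 8))) {
    expect_equal(d[pair[1], pair[2]],
                 nei_oracle(x[pair[1], ], x[pair[2], ]), tolerance = 1e-9)
  }
})

test_that("opposite homozygotes give the capped infinite Nei distance", {
  g <- toy_geno(rbind(A = c(0L, 0L, 0L), B = c(2L, 2L, 2L)), ids = c("A", "B"))
  expect_equal(nei_distance(g)["A", "B"], 1e9)
})

test_that("VanRaden GRM reproduces the single-locus case and duplicate pairs", {
  g <- toy_geno(rbind(A = 0L, B = 2L), ids = c("A", "B"))
  expect_equal(unname(vanraden_grm(g)),
               matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  cfg <- simulation_config(n_populations = 2, n_per_population = 100,
                           n_markers = 800, duplicate_rate = 0.05,
                           duplicate_error_rate = 0, missing_rate = 0,
                           parent_offspring_pairs = 0, seed = 12)
  sim <- simulate_panel(cfg)
  gm <- vanraden_grm(sim$genotypes)
  dp <- sim$truth$duplicate_pairs
  expect_true(all(gm[cbind(dp$id1, dp$id2)] >= 1.3))
})

test_that("GRM diagonal reflects inbreeding: trace/n near 1 + F", {
  for (f in c(0, 0.85)) {
    cfg <- simulation_config(n_populations = 1, n_per_population = 150,
                             n_markers = 1500, divergence_f = 0.05,
                             selfing_fis = f, admixture_alpha = 1,
                             duplicate_rate = 0, parent_offspring_pairs = 0,
                             missing_rate = 0, seed = 13)
    sim <- simulate_panel(cfg)
    gm <- vanraden_grm(sim$genotypes)
    expect_lt(abs(mean(diag(gm)) - (1 + f)), 0.05)
  }
})

test_that("method-of-moments IBD matches exhaustive enumeration on toys", {
  # 4 accessions, 3 markers, no missing: compare the per-locus IBS-state
  # expectations against without-replacement enumeration, then replicate the
  # full moment solution for one pair
  x <- rbind(A = c(0L, 1L, 2L), B = c(0L, 1L, 1L),
             C = c(2L, 0L, 0L), D = c(1L, 2L, 1L))
  g <- toy_geno(x, ids = rownames(x))
  tab <- mom_ibd(g, min_overlap = 1)

  alt <- colSums(x)
  nal <- rep(2 * nrow(x), 3)
  exp_l <- lapply(1:3, function(l) ibs_given_ibd_oracle(alt[l], nal[l]))
  for (pr in list(c("A", "B"), c("C", "D"), c("A", "D"))) {
    xi <- x[pr[1], ]; xj <- x[pr[2], ]
    ibs_state <- 2 - abs(xi - xj)
    o <- c(sum(ibs_state == 0), sum(ibs_state == 1), sum(ibs_state == 2))
    E00 <- sum(vapply(exp_l, function(e) e$ibd0[1], 0))
    E10 <- sum(vapply(exp_l, function(e) e$ibd0[2], 0))
    E20 <- sum(vapply(exp_l, function(e) e$ibd0[3], 0))
    E11 <- sum(vapply(exp_l, function(e) e$ibd1[2], 0))
    E21 <- sum(vapply(exp_l, function(e) e$ibd1[3], 0))
    z0 <- o[1] / E00
    z1 <- (o[2] - z0 * E10) / E11
    z2 <- (o[3] - z0 * E20 - z1 * E21) / 3
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    z <- z / sum(z)
    row <- tab[tab$id1 == pr[1] & tab$id2 == pr[2], ]
    expect_equal(c(row$z0, row$z1, row$z2), z, tolerance = 1e-9)
    expect_equal(row$pi_hat, z[2] / 2 + z[3], tolerance = 1e-9)
  }
})

test_that("IBD state probabilities form a simplex and duplicates hit pi-hat 1", {
  x <- rbind(A = c(0L, 1L, 2L, 1L, 0L), B = c(0L, 1L, 2L, 1L, 0L),
             C = c(2L, 0L, 0L, 1L, 2L))
  tab <- mom_ibd(toy_geno(x, ids = rownames(x)), min_overlap = 1)
  expect_true(all(abs(tab$z0 + tab$z1 + tab$z2 - 1) < 1e-9))
  ab <- tab[tab$id1 == "A" & tab$id2 == "B", ]
  expect_equal(ab$z2, 1)
  expect_equal(ab$pi_hat, 1)
  expect_equal(ab$ibs, 1)

  cfg <- simulation_config(n_populations = 2, n_per_population = 60,
                           n_markers = 600, seed = 14)
  sim <- simulate_panel(cfg)
  g <- impute_missing(sim$genotypes, seed = 1)
  tab <- mom_ibd(g)
  expect_true(all(abs(tab$z0 + tab$z1 + tab$z2 - 1) < 1e-9))
  expect_true(all(tab$pi_hat >= 0 & tab$pi_hat <= 1))
})

test_that("simulated parent-offspring pairs average pi-hat 0.5, unrelated near 0", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 200,
                           n_markers = 2000, divergence_f = 0.02,
                           selfing_fis = 0, admixture_alpha = 1,
                           duplicate_rate = 0, parent_offspring_pairs = 100,
                           missing_rate = 0, maf_floor = 0.1, seed = 11)
  sim <- simulate_panel(cfg)
  tab <- mom_ibd(sim$genotypes)
  key <- paste(tab$id1, tab$id2)
  tp <- sim$truth$relative_pairs
  po <- tab[key %in% c(paste(tp$id1, tp$id2), paste(tp$id2, tp$id1)), ]
  expect_equal(nrow(po), 100)
  expect_lt(abs(mean(po$pi_hat) - 0.5), 0.05)
  unrel <- tab[grepl("^ACC", tab$id1) & grepl("^ACC", tab$id2), ]
  expect_lt(mean(unrel$pi_hat), 0.05)
})

test_that("copy errors move duplicates apart: D up, pi-hat down in expectation", {
  d_by_err <- pi_by_err <- c()
  for (err in c(0, 0.02, 0.08)) {
    ds <- ps <- c()
    for (s in 1:3) {
      cfg <- simulation_config(n_populations = 1, n_per_population = 40,
                               n_markers = 500, duplicate_rate = 0.25,
                               duplicate_error_rate = err, missing_rate = 0,
                               parent_offspring_pairs = 0, seed = 100 + s)
      sim <- simulate_panel(cfg)
      pr <- pair_relatedness(sim$genotypes)
      key <- paste(pr$id1, pr$id2)
      dp <- sim$truth$duplicate_pairs
      sel <- key %in% c(paste(dp$id1, dp$id2), paste(dp$id2, dp$id1))
      ds <- c(ds, pr$d[sel]); ps <- c(ps, pr$pi_hat[sel])
    }
    d_by_err <- c(d_by_err, mean(ds)); pi_by_err <- c(pi_by_err, mean(ps))
  }
  expect_true(all(diff(d_by_err) > 0))
  expect_true(all(diff(pi_by_err) < 0))
})

test_that("percent IBD by collection matches enumeration on a 2x3 toy", {
  pairs <- data.frame(
    id1 = c("a1", "a1", "a2", "a1", "a2", "b1", "b1", "b2", "a1", "a2"),
    id2 = c("a2", "b1", "b1", "b2", "b2", "b2", "b3", "b3", "b3", "b3"),
    pi_hat = c(0, 0.8, 0, 0, 0, 0, 0, 0, 0, 0))
  pp <- data.frame(accession_id = c("a1", "a2", "b1", "b2", "b3"),
                   collection = c("A", "A", "B", "B", "B"))
  m <- percent_ibd_by_collection(pairs, pp)
  expect_equal(m["A", "B"], 100 * 1 / 6, tolerance = 1e-12)
  expect_equal(m["A", "A"], 0)
  expect_equal(m["B", "B"], 0)
  # within-collection of size 4 with all pairs related -> 100%
  pairs2 <- expand.grid(id1 = paste0("c", 1:4), id2 = paste0("c", 1:4),
                        stringsAsFactors = FALSE)
  pairs2 <- pairs2[pairs2$id1 < pairs2$id2, ]
  pairs2$pi_hat <- 1
  pp2 <- data.frame(accession_id = paste0("c", 1:4), collection = "C")
  expect_equal(percent_ibd_by_collection(pairs2, pp2)["C", "C"], 100)
})

test_that("regional IBD densities peak where relationships are planted", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 60,
                           n_markers = 800, duplicate_rate = 0.4,
                           duplicate_error_rate = 0.002,
                           parent_offspring_pairs = 0, missing_rate = 0,
                           regions = "DupLand", label_leakage = 0, seed = 15)
  sim <- simulate_panel(cfg)
  tab <- mom_ibd(sim$genotypes)
  dens <- ibd_density_by_region(tab, sim$passport)
  expect_true("DupLand" %in% names(dens))
  # duplicates put visible density mass near pi-hat 1
  expect_gt(dens$DupLand$peaks[which.max(dens$DupLand$peaks)], 0.9)
  # a region with fewer than two accessions is absent
  pp <- sim$passport
  pp$region[1] <- "Singleton"
  dens2 <- ibd_density_by_region(tab, pp)
  expect_false("Singleton" %in% names(dens2))
})
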