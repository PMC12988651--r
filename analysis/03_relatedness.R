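#!/usr/bin/env Rscript
# Stage 3 — pairwise relatedness.
#
# Computes Nei standard genetic distance and the VanRaden GRM on the
# cultivated dataset, and IBS plus method-of-moments genome-wide IBD
# (Z0/Z1/Z2, pi-hat) on the LD-pruned dataset; summarises the share of
# related pairs per collection pair and the pi-hat density per region.

library(genebankr)

cultivated <- read_vcf("results/cultivated.vcf")
pruned <- read_vcf("results/cultivated_pruned.vcf")
passport <- read_passport("results/panel/passport.csv")

pairs <- pair_relatedness(cultivated, pruned)
write.table(pairs, "results/pair_relatedness.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("%d pairs evaluated (n = %d accessions)\n",
            nrow(pairs), nrow(cultivated$dosages)))
cat(sprintf("pairs with pi-hat > 0.5 (duplicates/close kin): %d\n",
            sum(pairs$pi_hat > 0.5)))

pct <- percent_ibd_by_collection(pairs, passport)
write.table(round(pct, 2), "results/percent_ibd_by_collection.tsv",
            sep = "\t", quote = FALSE)
cat("percent pairs with pi-hat > 0 by collection pair:\n")
print(round(pct, 2))

dens <- ibd_density_by_region(pairs, passport)
peaks <- data.frame(
  region = names(dens),
  n_pairs = vapply(dens, function(d) d$n_pairs, 0),
  main_peak = vapply(dens, function(d) round(d$peaks[1], 3), 0))
write.table(peaks, "results/ibd_region_peaks.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("pi-hat density peaks per region:\n")
print(peaks, row.names = FALSE)
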