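#!/usr/bin/env Rscript
# Stage 2 — genotype quality control and marker filtering.
#
# Applies the call-rate exclusions (samples <= 0.50, markers <= 0.80),
# frequency-based imputation of remaining missing calls, heterozygosity
# exclusions (markers >= 0.4, samples >= 0.2) and the MAF >= 0.01 filter,
# producing the "cultivated" dataset used for relatedness.

library(genebankr)

g_raw <- read_vcf("results/panel/panel.vcf")
qc <- apply_qc_filters(g_raw, impute_seed = 43)
print(qc$report)

cultivated <- filter_maf(qc$genotypes, 0.01)
cat(sprintf("MAF filter: %d -> %d markers\n",
            ncol(qc$genotypes$dosages), ncol(cultivated$dosages)))

pruned <- ld_prune(cultivated)
cat(sprintf("LD pruning (50/5/0.5): %d -> %d markers\n",
            ncol(cultivated$dosages), ncol(pruned$dosages)))

dir.create("results", showWarnings = FALSE)
write_vcf(cultivated, "results/cultivated.vcf")
write_vcf(pruned, "results/cultivated_pruned.vcf")

pc <- pca_genotypes(cultivated, 4)
cat(sprintf("PCA: first two components explain %.1f%% + %.1f%% of variance\n",
            100 * pc$explained[1], 100 * pc$explained[2]))
write.table(data.frame(accession_id = cultivated$accession_ids,
                       round(pc$scores, 4)),
            "results/pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
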