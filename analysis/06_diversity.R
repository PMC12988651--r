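#!/usr/bin/env Rscript
# Stage 6 — per-group diversity, differentiation and AMOVA.
#
# Computes nucleotide diversity, observed/expected heterozygosity, F_IS,
# rarefied allelic richness and private alleles per genetic group
# (admixed accessions excluded), pairwise Weir-Cockerham F_ST, and a
# one-level AMOVA with 999 label permutations.

library(genebankr)

nonred <- read_vcf("results/nonredundant.vcf")
qtab <- read.delim("results/q_matrix.tsv",
                   colClasses = c(accession_id = "character"))
groups <- setNames(qtab$group, qtab$accession_id)[nonred$accession_ids]

assigned <- groups != "admixed"
cat(sprintf("%d assigned accessions (%d admixed excluded)\n",
            sum(assigned), sum(!assigned)))
g <- subset_genotypes(nonred, samples = assigned)
lab <- groups[assigned]

div <- per_group_diversity(g, lab)
div <- merge(div, allelic_richness(g, lab), by = "group")
div <- merge(div, private_alleles(g, lab), by = "group")
cat("diversity metrics per group:\n")
print(div, digits = 3, row.names = FALSE)
write.table(div, "results/diversity.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

fst <- pairwise_fst(g, lab)
cat("pairwise Weir-Cockerham F_ST:\n")
print(round(fst, 3))
write.table(round(fst, 5), "results/fst.tsv", sep = "\t", quote = FALSE)

am <- amova(g, lab, n_perm = 999, seed = 46)
print(am)
write.table(am$table, "results/amova.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
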