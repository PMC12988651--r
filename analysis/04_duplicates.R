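#!/usr/bin/env Rscript
# Stage 4 — duplicate detection and retention.
#
# Intersects the three relatedness criteria (Nei distance <= 0.03, GRM >= 1.3,
# pi-hat >= 0.6), confirms potential duplicates by passport name/alias
# matching, resolves retention per connected component and writes the
# non-redundant dataset.  Recall is assessed against the planted truth.

library(genebankr)

cultivated <- read_vcf("results/cultivated.vcf")
passport <- read_passport("results/panel/passport.csv")
pairs <- read.delim("results/pair_relatedness.tsv",
                    colClasses = c(id1 = "character", id2 = "character"))

potential <- flag_potential_duplicates(pairs, duplicate_criteria())
confirmed <- confirm_duplicates(potential, passport)
report <- resolve_retention(confirmed, cultivated, potential, passport)
print(report)

truth <- read.delim("results/panel/truth_pairs.tsv",
                    colClasses = "character")
dup <- truth[truth$relationship == "duplicate", ]
dup <- dup[dup$id1 %in% cultivated$accession_ids &
             dup$id2 %in% cultivated$accession_ids, ]
key <- paste(potential$id1, potential$id2)
recall <- mean(paste(dup$id1, dup$id2) %in% key |
                 paste(dup$id2, dup$id1) %in% key)
cat(sprintf("recall on planted duplicates surviving QC: %.1f%% (%d pairs)\n",
            100 * recall, nrow(dup)))

write.table(potential, "results/potential_duplicates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(confirmed, "results/confirmed_duplicates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(accession_id = report$removed),
            "results/removed_accessions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

nonred <- filter_maf(subset_genotypes(
  cultivated, samples = cultivated$accession_ids %in% report$retained), 0.01)
write_vcf(nonred, "results/nonredundant.vcf")
write_vcf(ld_prune(nonred), "results/nonredundant_pruned.vcf")
cat(sprintf("non-redundant dataset: %d accessions x %d markers\n",
            nrow(nonred$dosages), ncol(nonred$dosages)))
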