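#!/usr/bin/env Rscript
# Stage 7 — geographic enrichment of genetic groups.
#
# Tests, per genetic group, whether ancestry proportions (Q values) differ
# across geographic regions: Kruskal-Wallis gate, Bonferroni-corrected
# pairwise Wilcoxon tests with a compact letter display, and rarefaction of
# every region to equal size (50 accessions, 500 replicates) to remove
# sample-size bias.  Regions with fewer than 10 accessions are removed.

library(genebankr)

nonred <- read_vcf("results/nonredundant.vcf")
passport <- read_passport("results/panel/passport.csv")
qtab <- read.delim("results/q_matrix.tsv",
                   colClasses = c(accession_id = "character"))
qcols <- grep("^Q[0-9]+$", names(qtab))
Q <- as.matrix(qtab[, qcols])
rownames(Q) <- qtab$accession_id
regions <- setNames(passport$region, passport$accession_id)[rownames(Q)]

kw <- kruskal_wallis_by_group(Q, regions, min_region = 10)
cat("Kruskal-Wallis per group (regions with n >= 10):\n")
print(kw, digits = 4, row.names = FALSE)

enr <- rarefied_enrichment(Q, regions, size = 50, reps = 500, seed = 47)
print(enr)

cat("\nfull-data means with compact letters:\n")
for (fd in enr$full_data) {
  cat(sprintf("  %s (KW p = %.3g)%s\n", fd$group, fd$kw_p,
              if (!is.na(fd$enriched_region))
                paste0("  enriched in ", fd$enriched_region) else ""))
  m <- fd$means[order(fd$means, decreasing = TRUE)]
  for (r in names(m)) {
    cat(sprintf("    %-15s mean Q %.3f  %s\n", r, m[r], fd$letters[r]))
  }
}

write.table(kw, "results/kruskal_wallis.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(enr$summary, "results/enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
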