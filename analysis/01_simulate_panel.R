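#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study panel.
#
# Builds a three-population, highly selfing SNP panel (340 accessions x
# 2 000 markers) with planted duplicates, parent-offspring pairs and
# ancestry-correlated passport labels, and exports it as plain-text
# fixtures for the downstream stages.

library(genebankr)

out <- "results/panel"
cfg <- simulation_config(seed = 42)      # study conditions: defaults
sim <- simulate_panel(cfg)
paths <- export_fixture(sim, out)

cat(sprintf("panel: %d accessions x %d markers\n",
            nrow(sim$genotypes$dosages), ncol(sim$genotypes$dosages)))
cat(sprintf("planted: %d duplicate pairs, %d parent-offspring pairs\n",
            nrow(sim$truth$duplicate_pairs), nrow(sim$truth$relative_pairs)))
cat("wrote:", paste(basename(paths), collapse = ", "), "->", out, "\n")
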