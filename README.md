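# genebankr

Genotype-based curation and diversity analysis of crop genebank collections.

Genebanks conserve tens of thousands of accessions per crop, and decades of
re-collection and germplasm exchange leave them salted with duplicates —
identical landraces entered under different numbers, or the same breeding
line deposited in several collections.  Redundancy inflates curation costs
and biases diversity estimates, but flagging duplicates from passport
records alone is unreliable.  `genebankr` implements the genotype-first
alternative for SNP-genotyped collections of predominantly selfing crops
(cowpea being the motivating case): screen every accession pair with
multiple relatedness metrics, confirm candidates against passport
names/aliases, and carry the de-duplicated panel into population structure,
diversity and geographic-enrichment analyses.  It is aimed at genebank
curators and population geneticists working with biallelic SNP panels (VCF
with GT calls) and passport metadata.

## What it computes

* **QC and marker filtering** — call-rate exclusions (samples ≤ 0.50,
  markers ≤ 0.80), frequency-based imputation, heterozygosity exclusions
  (markers ≥ 0.4, samples ≥ 0.2), MAF ≥ 0.01, and `--indep-pairwise`-style
  LD pruning (50/5/0.5).
* **Pairwise relatedness** — Nei (1972) standard genetic distance between
  accessions, *D = −ln(J_xy/√(J_x J_y))*; VanRaden method-1 genomic
  relationship matrix, *G = ZZ′ / 2Σp_j(1−p_j)*; identity-by-state; and
  method-of-moments genome-wide identity-by-descent *(Ẑ₀, Ẑ₁, Ẑ₂)* with
  *π̂ = Ẑ₁/2 + Ẑ₂*, using exact finite-sample (without-replacement)
  IBS-state expectations.
* **Duplicate detection** — a pair is a *potential duplicate* iff
  *D ≤ 0.03* and *G ≥ 1.3* and *π̂ ≥ 0.6*; it is *confirmed* iff the two
  accessions share a normalised passport name or alias.  Connected
  components of confirmed pairs are resolved by retaining the member with
  the best pre-imputation call rate.
* **Ancestry and K selection** — sparse-NMF-style estimation of admixture
  coefficients *Q* (one-hot genotype encoding, alternating simplex-projected
  least squares with a monotone-loss guarantee), masked cross-entropy and
  Evanno ΔK model selection, 70% membership group assignment.
* **Diversity and differentiation** — per-group nucleotide diversity π,
  H_O/H_E, weighted F_IS, Hurlbert rarefied allelic richness, private
  alleles, pairwise Weir–Cockerham F_ST, and one-level AMOVA with
  permutation p-values.
* **Geographic enrichment** — per-group Kruskal–Wallis tests of *Q* across
  regions, Bonferroni-corrected pairwise Wilcoxon tests with compact letter
  displays, and rarefaction of regions to equal size (50 accessions,
  500 replicates) to remove sample-size bias.
* **Synthetic panels with planted truth** — a Balding–Nichols /
  Dirichlet-admixture / excess-homozygosity generator with planted
  duplicates, parent–offspring pairs and ancestry-correlated passport
  labels, so every stage is validated against known answers.

See `vignettes/genebank-curation-methods.Rmd` for the estimators, defaults
and design decisions in full.

## Worked example

Simulate a selfing three-population panel with planted duplicates, run QC
and relatedness, and resolve the duplicates:

```r
library(genebankr)

sim <- simulate_panel(simulation_config(seed = 42))   # 340 x 2000, 30 planted duplicate pairs
qc  <- apply_qc_filters(sim$genotypes, impute_seed = 43)
print(qc$report)
#> QC report
#>   samples: 340 -> 330 (call rate -0, heterozygosity -10)
#>   markers: 2000 -> 2000 (call rate -0, heterozygosity -0)

cultivated <- filter_maf(qc$genotypes, 0.01)
pairs <- pair_relatedness(cultivated, ld_prune(cultivated))
pot   <- flag_potential_duplicates(pairs)
conf  <- confirm_duplicates(pot, sim$passport)
report <- resolve_retention(conf, cultivated, pot, sim$passport)
print(report)
#> duplicate report
#>   potential pairs: 29
#>   confirmed pairs: 23
#>   components: 23  removed: 23  retained: 307
#>   within/between-collection % (potential):  34.5 / 65.5
#>   within/between-collection % (confirmed):  30.4 / 69.6
```

Reading the output: the ten removed samples are the planted outbred
parent–offspring progeny, excluded by the heterozygosity filter exactly as
intended for a selfing crop.  Of the 30 planted duplicate pairs, 29 pass all
three relatedness criteria (one copy drifted past a threshold through its
simulated genotyping errors) and 23 also share an alias — the generator
plants aliases on 80% of duplicates — so 23 redundant accessions are removed
and 307 retained.  The potential/confirmed split across collections mirrors
the planted design, where duplicates are deposited into random collections.

The full analysis — structure, diversity, AMOVA, geographic enrichment — is
scripted as numbered drivers that write their tables under `results/`:

```sh
Rscript analysis/01_simulate_panel.R
Rscript analysis/02_quality_control.R
Rscript analysis/03_relatedness.R
Rscript analysis/04_duplicates.R
Rscript analysis/05_structure.R      # cross-entropy elbow recovers K = 3
Rscript analysis/06_diversity.R      # per-group pi/F_IS/F_ST, AMOVA p = 0.001
Rscript analysis/07_geo_enrichment.R # planted regional enrichment, 100% of replicates
```

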