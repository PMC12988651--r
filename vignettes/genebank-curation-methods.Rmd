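---
title: "Methods: genotype-based curation and diversity analysis of genebank collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-based curation and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`genebankr` implements a curation workflow for SNP-genotyped crop genebank
collections: genotype quality control; pairwise relatedness; multi-criteria
duplicate-accession detection with passport confirmation; ancestry estimation
and genetic-group assignment; per-group diversity statistics with AMOVA; and
rarefaction-based geographic enrichment tests.  The workflow is exercised end
to end on synthetic panels with planted truth (`analysis/01...07`), so every
stage can be validated against known duplicates, relatives and admixture
proportions.  This vignette records the models, estimators, parameter
defaults and design choices, and what the synthetic validation does and does
not establish.

# The synthetic panel generator

`simulate_panel()` emulates a highly selfing diploid crop genotyped at a few
thousand biallelic SNPs, such as cowpea (reported outcrossing rates are 0-5%,
and panel-wide inbreeding coefficients around 0.77-0.94 are typical).

* **Allele frequencies.** Ancestral frequencies are Uniform(`maf_floor`,
  1 − `maf_floor`); each of K populations drifts under a Balding-Nichols
  model: `p_k ~ Beta(p(1−f)/f, (1−p)(1−f)/f)` with `f = divergence_f`.
  The default `f = 0.3` produces strong, easily recoverable structure
  (multi-locus F_ST around 0.2 between groups).
* **Admixture.** Per-accession proportions are symmetric
  Dirichlet(`admixture_alpha`); the *true population* label is the
  majority-ancestry component.  Small `alpha` (default 0.2) gives mostly
  near-pure accessions with an admixed minority, mirroring a structured
  germplasm panel.  As `alpha → 0` the Dirichlet degenerates to a random
  vertex; the generator handles the numerical underflow explicitly.
* **Selfing.** Rather than simulating generations of self-fertilisation,
  genotypes are drawn with excess homozygosity directly from each accession's
  admixed frequency `π`: P(2) = π² + Fπ(1−π), P(1) = 2π(1−π)(1−F),
  P(0) = (1−π)² + Fπ(1−π), with `F = selfing_fis` (default 0.85, the centre
  of the range above).  This is simpler and matches the F_IS statistics the
  workflow estimates; a one-population panel at `F = 0.9` recovers
  F̂_IS within ±0.05 (tested).
* **Planted duplicates** copy a base accession's genotype and then flip one
  allele per call with probability `duplicate_error_rate` (default 0.005),
  mimicking re-collection/regeneration of the same landrace plus genotyping
  error; with probability `alias_share_prob` the duplicate carries its
  source's name as a passport alias.  The default `duplicate_rate = 0.10`
  reflects the roughly one-in-ten duplication levels reported for
  well-curated crop collections.
* **Planted parent-offspring pairs** inherit one allele from the parent
  genotype and one drawn from the parent's population frequency (an outbred
  union), so their expected genome-wide IBD is π̂ = 0.5.
* **Passport labels.** Region (and country) track the majority population
  with a configurable `label_leakage` (default 0.1), so geographic
  enrichment has a planted signal; collections are assigned at random, so
  duplicate pairs fall both within and between collections.

**What the generator does not emulate:** linkage and recombination maps
(markers are unlinked, so LD pruning removes almost nothing on synthetic
panels — its logic is therefore tested against planted correlated columns
and a brute-force reference pruner instead), within-accession heterogeneity,
genotyping platform artefacts such as allele dropout, and non-random
missingness.  Passing tests demonstrate correctness of the estimators and
calibration of the decision rules under the stated model, not robustness to
those real-data complications.

# Quality control

`apply_qc_filters()` applies, in order: (1) drop samples with call rate
≤ 0.50; (2) drop markers with call rate ≤ 0.80; (3) impute remaining missing
genotypes; (4) drop markers with heterozygosity ≥ 0.4, then samples with
heterozygosity ≥ 0.2.  All boundaries are inclusive exactly as written.
Whether heterozygosity should be assessed before or after imputation is
genuinely open; the default is post-imputation (pass `impute_seed`), and
passing `impute_seed = NULL` assesses it missing-aware instead.

`impute_missing()` is a deliberately simple frequency-sampling imputer: each
missing call is two alleles drawn from the marker's observed frequency
(Binomial(2, p) dosage).  LD-aware phasing imputation is out of scope here;
downstream metrics need complete dosages, not haplotypes, and the workflow's
relatedness statistics average over thousands of markers, where unbiased
marginal fills are adequate.  Non-missing calls are never altered, and a
fully missing marker is left missing and flagged.

MAF filtering retains markers with MAF ≥ 0.01 (inclusive).  LD pruning
follows the common `--indep-pairwise 50 5 0.5` scheme: 50-marker windows
advanced by 5; within a window, while any retained pair has squared dosage
correlation above 0.5, the lower-MAF member is removed (ties remove the
higher index).  r² is the squared Pearson correlation of dosages (not
haplotype D′): deterministic and adequate for thinning to quasi-independent
loci, without chasing bit-exactness with any particular tool.

# Relatedness

* **Nei (1972) standard distance between accessions.**  Each accession is a
  one-individual population with per-locus allele frequencies 0/0.5/1;
  identities J_x, J_y, J_xy are averaged over pairwise-complete loci and
  D = −ln(J_xy/√(J_x J_y)).  When J_xy = 0 (opposite homozygotes everywhere)
  the distance is infinite and stored as the cap 1e9 to keep matrices
  numeric.
* **VanRaden (method 1) GRM.**  G = ZZ′/(2Σp(1−p)) with Z the dosage matrix
  centred by twice the panel frequency; frequencies come from the analysed
  panel itself (no external reference).  On simulated panels the mean
  diagonal is ≈ 1 + F (tested at F = 0 and 0.85).
* **Genome-wide IBD.**  `mom_ibd()` implements method-of-moments estimation
  of P(IBD = 0, 1, 2) from observed IBS-state counts, in the style of the
  common `--genome` analysis.  The expected IBS-state probabilities given
  each IBD state are computed *exactly* for finite samples, as
  without-replacement allele draws from the marker's observed allele pool
  (ratios of falling factorials), rather than with approximate correction
  factors; this makes the estimator agree to numerical precision with an
  enumeration oracle, which the tests exploit.  Estimates are clamped to
  [0, 1], renormalised to sum to 1, and summarised as π̂ = Z1/2 + Z2.
  Loci with fewer than four observed alleles carry no moment information and
  are excluded from both observed and expected counts.

  A known property of moment-based IBD inherited here: allele frequencies
  are estimated panel-wide, so in strongly structured panels,
  within-population pairs show inflated π̂ relative to pedigree expectations.
  Duplicate detection is unaffected (its π̂ ≥ 0.6 threshold sits far above
  the background), but per-region IBD summaries should be read with this in
  mind.

# Duplicate detection

A pair is a *potential duplicate* when all three criteria hold (boundaries
inclusive): Nei distance ≤ 0.03, GRM ≥ 1.3 and π̂ ≥ 0.6.  The distance
criterion is a small-distance rule (small D = similar); the 0.03/1.3/0.6
defaults are conservative screening thresholds for near-identical material.
A potential pair is *confirmed* only when the two accessions share a
normalised name or alias (uppercase, all whitespace/punctuation stripped; an
empty result never matches).  Normalisation is deliberately conservative —
no fuzzy matching — to avoid false merges; the name gate drives false
confirmations among unrelated, uniquely named accessions to zero (tested).

Confirmed pairs define a graph; connected components (not cliques) form
duplicate sets, since linked pairs A–B, B–C describe one redundant set even
if A–C was not flagged.  Within each component the accession with the
highest pre-imputation call rate is retained (ties break to the
lexicographically smallest ID).  The exact multi-member retention policy a
curator would use is under-specified in general; this rule is a documented,
deterministic stand-in, and the report keeps all pairs so a curator can
override it.

# Ancestry estimation and K selection

`estimate_ancestry()` is a nonnegative matrix factorisation estimator in the
sNMF family, standing in for the three commonly used clustering programs
(Bayesian MCMC, likelihood block-relaxation, sNMF) — appropriate because on
strongly structured data their admixture estimates coincide, and the NMF
formulation avoids Hardy-Weinberg and linkage-equilibrium assumptions that
selfing crops violate.  Genotypes are one-hot encoded to an n × 3L indicator
matrix Y and factorised as Y ≈ QF with the rows of Q and each per-locus
3-block of F constrained to the probability simplex.  Updates alternate
ridge-regularised least squares (ridge `alpha` on Q, default 0) with
Euclidean simplex projection; because the simplex is convex, backtracking
along the segment to the previous iterate guarantees a non-increasing loss,
which is asserted for every run in the tests.  Convergence is declared at a
relative loss change below 1e-6 (cap 200 iterations); `restarts` random
initialisations (default 5) guard against local optima.  Column order is
arbitrary (label switching); validation aligns columns by the RMSE-optimal
permutation (`align_q_columns()`).

A note on resolution: least-squares Q estimates of truly pure accessions are
bounded at the simplex vertex, so one-sided truncation noise of order
1/√(L·divergence) leaves typical maximum memberships at 0.95-0.99 rather
than exactly 1.  The purity recovery test therefore uses a 5 000-marker
panel, where ≥95% of unadmixed accessions exceed 0.95 membership.

Two K-selection criteria are reported rather than adjudicated:

* **Masked cross-entropy** (`select_k_cross_entropy()`): a fraction
  (default 5%) of genotype entries is replaced by the locus mean genotype
  distribution, the model is fitted, and the cross-entropy of predicted
  genotype probabilities on the masked entries is averaged over replicates;
  the suggested K is the elbow (maximum second difference) of the mean
  curve, with the minimum-cross-entropy K also reported.
* **Evanno delta-K** (`evanno_delta_k()`): |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))
  over replicate objective values.  Computed here from NMF final losses as
  an *analogue* of the original log-likelihood formulation, not a replica;
  it shares the known bias of the method toward the uppermost hierarchy
  level.  Both criteria are emitted and the choice of K is left to the user;
  the analysis driver uses the cross-entropy elbow.

Accessions are assigned to their maximum-Q group when that maximum is at
least 0.70 (inclusive), otherwise labelled admixed; argmax ties break to the
lowest group index.

# Diversity, F-statistics and AMOVA

Per locus and group: nucleotide diversity uses the unbiased combinatorial
estimator π = 1 − Σ_a C(n_a,2)/C(n,2) over allele counts; H_E is the plain
1 − Σp² (no small-sample correction — the two choices are deliberate and
documented since different toolkits differ); H_O is the heterozygous-call
fraction.  Group summaries are means across loci weighted by the non-missing
allele count, and F_IS = 1 − Σ(w·H_O)/Σ(w·H_E) as a ratio of weighted sums,
which is robust to monomorphic loci.  Allelic richness is Hurlbert
rarefaction Σ_a [1 − C(N−N_a, g)/C(N, g)] per locus (mean over loci), with
the automatic rarefaction size the largest value every group supports at
every locus; computed via log-binomial coefficients for numerical stability.
Private alleles count (locus, allele) combinations observed in exactly one
group.

Pairwise F_ST uses the Weir-Cockerham (1984) variance components a, b, c per
locus with the multi-locus ratio of sums Σa/Σ(a+b+c); negative per-locus
components are retained before summation and slightly negative estimates are
reported as computed (not floored) to preserve unbiasedness.  The
implementation is verified against an independent transcription of the
published formulas on toy panels to 1e-12.

AMOVA is implemented at one hierarchy level on squared Euclidean distances
between dosage vectors: SSDs from within-group distance sums,
variance components from the expected mean squares with the standard
group-size weighting n₀, Φ_ST = σ²_among/(σ²_among + σ²_within), and the
permutation p-value (1 + #{Φ_perm ≥ Φ}) / (n_perm + 1) under random label
reassignment (999 permutations by default, so the smallest attainable p is
0.001).  Negative components are truncated at zero for the percentage
display only.  Sums of squares agree with the distance-based partition
computed independently by `vegan::adonis2` (tested).  Admixed accessions are
excluded from all group-wise statistics.

# Geographic enrichment

Ancestry proportions (Q values), not hard assignments, are the response.
Regions with fewer than 10 accessions are removed.  Per group: a
Kruskal-Wallis rank-sum test (midranks, tie-corrected H, chi-square
approximation) gates Bonferroni-corrected two-sided pairwise Wilcoxon tests
(exact enumeration when both sides have ≤ 8 observations and no ties; normal
approximation with tie correction otherwise).  The Bonferroni multiplier is
the number of region pairs within that group's family — correction is per
group, not across groups, matching the per-group testing structure.
Non-significant pairs define a graph summarised by an insert-and-absorb
compact letter display.

*Enrichment* of a group in a region is not a universally standardised call;
the rule here is: the region has the highest mean Q **and** differs
significantly (adjusted p < 0.05) from every other region.  It is applied to
the full data and within each rarefaction replicate.  Rarefaction draws
`size = 50` accessions per region without replacement over `reps = 500`
replicates; regions smaller than the rarefaction size are excluded rather
than resampled, since sampling with replacement would misstate their
evidence.  The replicate-significant fraction is reported per (group,
region) and its interpretation (e.g. majority vote) is left to the user.
Under exchangeable regions the call rate stays below 10%, and the
Kruskal-Wallis type-I error is 0.05 ± 0.02 (both tested).

# Numerical choices and degenerate inputs

* Missing genotypes are `NA`; dosage values are restricted to {0, 1, 2, NA}
  and validated at construction.
* Infinite Nei distances are capped at 1e9; pairs with no overlapping loci
  are `NA`.
* IBD clamping order: clamp Z0, Z1, Z2 to [0, 1], renormalise to sum 1, then
  compute π̂.
* Monomorphic markers are tolerated everywhere: they contribute nothing to
  the GRM denominator, no moment information to IBD, zero diversity and
  richness 1.
* Zero-variance inputs: constant Q columns give H = 0, p = 1 in the
  Kruskal-Wallis test; constant densities fall back to a fixed bandwidth.
* All randomness (imputation, masking, NMF initialisation, permutations,
  rarefaction) flows from explicit integer seeds through isolated RNG
  streams that do not disturb the caller's RNG state; fixed seeds give
  byte-identical artifacts (tested).

# Problem sizes

The analysis drivers use a 340-accession × 2 000-marker panel with K = 3
populations, which the full workflow processes in a few minutes on one core
— large enough for all decision rules to operate at realistic signal levels,
small enough to iterate on.  Tests use panels from 4 × 3 toys (exact
oracles) to 400 × 5 000 (estimator resolution).  The workflow itself scales
to genebank-sized panels (10⁴ accessions) since all pair-level computations
are BLAS matrix products, though the O(n²) pair table then requires tens of
gigabytes and hours rather than seconds; chunked evaluation would be the
natural extension and is out of scope here.

# Known limitations

* The imputer ignores LD; rare-allele calls at low call-rate markers are
  noisier than a haplotype-aware method would give.
* Moment-based IBD is biased upward within subpopulations when frequencies
  are estimated panel-wide (see above).
* The NMF estimator reports point estimates only — no assignment
  uncertainty; group assignment at 0.70 is a hard threshold.
* One-level AMOVA only; nested designs (e.g. region within continent) are
  not implemented.
* Name normalisation will not match genuinely different spellings
  ("IT97K-499-35" vs "IT97K-499/35" do match; "IT97K" vs "IT-97-K" also
  match; but "Blackeye" vs "Black eyed pea" do not), which is the intended
  conservative behaviour.
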