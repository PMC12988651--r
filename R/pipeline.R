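#' Configuration for the end-to-end curation pipeline
#'
#' Collects every stage threshold in one place.  Defaults are the standard
#' operating values of the workflow: call-rate exclusions at 0.50 (samples)
#' and 0.80 (markers), heterozygosity exclusions at 0.4 (markers) and 0.2
#' (samples), MAF 0.01, LD pruning 50/5/0.5, duplicate criteria 0.03 (Nei) /
#' 1.3 (GRM) / 0.6 (pi-hat), 70% Q-membership assignment, 999 AMOVA
#' permutations, rarefaction to 50 over 500 replicates and a 10-accession
#' region minimum.
#'
#' @param input either a [simulation_config] or a list with paths `vcf` and
#'   `passport`.
#' @param out_dir directory for per-stage artifacts, or NULL to skip writing.
#' @param seed integer master seed for all stochastic stages.
#' @param sample_cr_max_excl,marker_cr_max_excl,marker_het_min_excl,sample_het_min_excl
#'   QC thresholds (see [apply_qc_filters()]).
#' @param maf_min MAF retention threshold.
#' @param ld_window,ld_step,ld_r2_max LD pruning parameters.
#' @param dup_d_max,dup_g_min,dup_pihat_min duplicate criteria.
#' @param k_structure number of ancestral populations fitted, or NULL to pick
#'   the cross-entropy elbow over `k_range`.
#' @param k_range K values scanned when `k_structure` is NULL.
#' @param k_reps cross-entropy replicates per K.
#' @param q_threshold group-membership threshold.
#' @param amova_n_perm AMOVA permutations.
#' @param rarefaction_size,rarefaction_reps rarefied enrichment parameters.
#' @param min_region minimum region size for enrichment tests.
#' @param structure_restarts NMF restarts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = simulation_config(),
                            out_dir = NULL,
                            seed = 1L,
                            sample_cr_max_excl = 0.50,
                            marker_cr_max_excl = 0.80,
                            marker_het_min_excl = 0.4,
                            sample_het_min_excl = 0.2,
                            maf_min = 0.01,
                            ld_window = 50, ld_step = 5, ld_r2_max = 0.5,
                            dup_d_max = 0.03, dup_g_min = 1.3,
                            dup_pihat_min = 0.6,
                            k_structure = NULL,
                            k_range = 1:6,
                            k_reps = 3,
                            q_threshold = 0.70,
                            amova_n_perm = 999,
                            rarefaction_size = 50,
                            rarefaction_reps = 500,
                            min_region = 10,
                            structure_restarts = 3) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full curation and diversity pipeline
#'
#' Stages, in order: ingest or simulate -> QC (call rates, imputation,
#' heterozygosity) -> MAF filter ("cultivated" dataset) -> Nei distance + GRM
#' -> LD pruning ("cultivated-pruned") -> method-of-moments IBD -> duplicate
#' flagging, passport confirmation and retention -> removal of duplicates and
#' MAF refilter ("non-redundant") -> LD pruning ("non-redundant pruned") ->
#' ancestry estimation and group assignment -> per-group diversity, pairwise
#' F_ST and AMOVA -> geographic enrichment.  When `config$out_dir` is set,
#' per-stage TSV artifacts and a JSON summary are written.
#'
#' @param config a [pipeline_config].
#' @return list with the per-stage objects and a `summary` list of headline
#'   counts (pairs evaluated, potential/confirmed duplicates, retained
#'   accessions, chosen K, group sizes).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- NULL
  if (inherits(cf$input, "simulation_config")) {
    sim <- stage("simulate", simulate_panel(cf$input))
    g_raw <- sim$genotypes
    passport <- sim$passport
  } else {
    g_raw <- stage("ingest", read_vcf(cf$input$vcf))
    passport <- stage("ingest", read_passport(cf$input$passport))
  }
  pre_impute_cr <- call_rates(g_raw)$sample

  qc <- stage("qc", apply_qc_filters(
    g_raw,
    sample_cr_max_excl = cf$sample_cr_max_excl,
    marker_cr_max_excl = cf$marker_cr_max_excl,
    marker_het_min_excl = cf$marker_het_min_excl,
    sample_het_min_excl = cf$sample_het_min_excl,
    impute_seed = cf$seed + 1L))
  g_qc <- qc$genotypes

  cultivated <- stage("maf", filter_maf(g_qc, cf$maf_min))
  n <- nrow(cultivated$dosages)

  cultivated_pruned <- stage("ld_prune", ld_prune(
    cultivated, cf$ld_window, cf$ld_step, cf$ld_r2_max))

  pairs <- stage("relatedness", pair_relatedness(cultivated, cultivated_pruned))

  crit <- duplicate_criteria(cf$dup_d_max, cf$dup_g_min, cf$dup_pihat_min)
  potential <- stage("dedup", flag_potential_duplicates(pairs, crit))
  confirmed <- stage("dedup", confirm_duplicates(potential, passport))
  # retention uses pre-imputation call rates from the raw panel
  g_for_retention <- cultivated
  cr_raw <- pre_impute_cr[cultivated$accession_ids]
  report <- stage("dedup", {
    rep_ <- resolve_retention(confirmed, cultivated, potential, passport)
    # recompute retention on raw call rates
    if (length(rep_$components)) {
      keep_of <- vapply(rep_$components, function(members) {
        r <- cr_raw[members]
        best <- members[r == max(r)]
        sort(best)[1]
      }, "")
      removed <- sort(setdiff(unlist(rep_$components), keep_of))
      rep_$removed <- removed
      rep_$retained <- setdiff(cultivated$accession_ids, removed)
    }
    rep_
  })

  nonred <- stage("nonredundant", {
    keep <- cultivated$accession_ids %in% report$retained
    filter_maf(subset_genotypes(cultivated, samples = keep), cf$maf_min)
  })
  nonred_pruned <- stage("ld_prune", ld_prune(
    nonred, cf$ld_window, cf$ld_step, cf$ld_r2_max))

  ksel <- NULL
  k_use <- cf$k_structure
  if (is.null(k_use)) {
    ksel <- stage("structure", select_k_cross_entropy(
      nonred_pruned, K_range = cf$k_range, reps = cf$k_reps,
      seed = cf$seed + 2L))
    k_use <- ksel$k_elbow
  }
  anc <- stage("structure", estimate_ancestry(
    nonred_pruned, K = k_use, seed = cf$seed + 3L,
    restarts = cf$structure_restarts))
  groups <- assign_groups(anc, cf$q_threshold)

  assigned <- groups != "admixed"
  div <- fst <- am <- NULL
  if (length(unique(groups[assigned])) >= 2) {
    g_assigned <- subset_genotypes(nonred, samples = assigned)
    lab <- groups[assigned]
    div <- stage("diversity", per_group_diversity(g_assigned, lab))
    rich <- stage("diversity", allelic_richness(g_assigned, lab))
    div <- merge(div, rich, by = "group")
    div <- merge(div, private_alleles(g_assigned, lab), by = "group")
    fst <- stage("diversity", pairwise_fst(g_assigned, lab))
    am <- stage("amova", amova(g_assigned, lab, n_perm = cf$amova_n_perm,
                               seed = cf$seed + 4L))
  }

  enr <- NULL
  regions <- stats::setNames(passport$region, passport$accession_id)
  reg_nonred <- regions[nonred$accession_ids]
  elig <- sum(table(reg_nonred) >= cf$rarefaction_size)
  if (elig >= 2) {
    enr <- stage("enrichment", rarefied_enrichment(
      anc, reg_nonred, size = cf$rarefaction_size,
      reps = cf$rarefaction_reps, seed = cf$seed + 5L))
  }

  summary <- list(
    n_input = nrow(g_raw$dosages),
    n_after_qc = nrow(g_qc$dosages),
    n_markers_cultivated = ncol(cultivated$dosages),
    n_markers_cultivated_pruned = ncol(cultivated_pruned$dosages),
    n_accessions = n,
    pairs_evaluated = pair_count(n),
    potential_duplicate_pairs = nrow(potential),
    confirmed_duplicate_pairs = nrow(confirmed),
    duplicate_accessions_removed = length(report$removed),
    n_retained = length(report$retained),
    n_markers_nonredundant = ncol(nonred$dosages),
    n_markers_nonredundant_pruned = ncol(nonred_pruned$dosages),
    chosen_k = k_use,
    group_sizes = as.list(table(groups)),
    n_admixed = sum(!assigned),
    amova_pct_among = if (!is.null(am)) unname(am$variance_pct["among"]) else NULL,
    amova_p = if (!is.null(am)) am$p_value else NULL,
    seed = cf$seed
  )
  stopifnot(summary$n_retained + summary$duplicate_accessions_removed ==
              summary$n_accessions)

  result <- list(genotypes_raw = g_raw, passport = passport,
                 truth = if (!is.null(sim)) sim$truth else NULL,
                 qc_report = qc$report,
                 cultivated = cultivated,
                 cultivated_pruned = cultivated_pruned,
                 pairs = pairs,
                 duplicate_report = report,
                 nonredundant = nonred,
                 nonredundant_pruned = nonred_pruned,
                 k_selection = ksel,
                 ancestry = anc,
                 groups = groups,
                 diversity = div,
                 fst = fst,
                 amova = am,
                 enrichment = enr,
                 summary = summary)

  if (!is.null(cf$out_dir)) {
    write_pipeline_artifacts(result, cf$out_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(result$pairs, "pair_relatedness.tsv")
  wt(result$duplicate_report$confirmed_pairs, "confirmed_duplicates.tsv")
  wt(data.frame(accession_id = result$duplicate_report$removed),
     "removed_accessions.tsv")
  if (!is.null(result$diversity)) wt(result$diversity, "diversity.tsv")
  if (!is.null(result$fst)) {
    utils::write.table(result$fst, file.path(out_dir, "fst.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(result$amova)) wt(result$amova$table, "amova.tsv")
  if (!is.null(result$enrichment)) wt(result$enrichment$summary,
                                      "enrichment.tsv")
  q <- result$ancestry$Q
  wt(data.frame(accession_id = rownames(q), q,
                group = result$groups, check.names = FALSE), "q_matrix.tsv")
  jsonlite::write_json(result$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
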