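#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file with GT genotypes into ALT-allele dosages.  Phase is
#' ignored (`0|1` and `0/1` both give dosage 1); any GT containing `.` becomes
#' missing.  Multi-allelic records are rejected.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(gt_fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    stop("VCF records lack a GT field", call. = FALSE)
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records are not supported", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) {
    stop("duplicate sample names in VCF", call. = FALSE)
  }
  # dosage = ALT allele count; any '.' in the call -> NA
  gt_chr <- sub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(gt),
                dimnames = list(samples, NULL))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  vals <- lut[gt_chr]
  dos[] <- t(matrix(vals, nrow = nrow(gt)))
  markers <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, markers, accession_ids = samples)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write a genotype matrix to a minimal VCF 4.2 file
#'
#' Emits biallelic records with a GT-only FORMAT; missing genotypes are
#' written as `./.`.  Round-trips losslessly through [read_vcf()].
#'
#' @param g a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=genebankr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$accession_ids), collapse = "\t")
  ), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gtxt <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(g$markers$chrom[j], g$markers$pos[j],
                       paste0("snp", j), g$markers$ref[j], g$markers$alt[j],
                       ".", "PASS", ".", "GT", gtxt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a passport table
#'
#' @param path CSV file with columns `accession_id`, `name`, `aliases`
#'   (semicolon-separated), `collection`, `country`, `region`,
#'   `improvement_status`, `cultivar_group`.
#' @return a data.frame with one row per accession.
#' @export
read_passport <- function(path) {
  pp <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_passport(pp)
  pp
}

#' Write a passport table as CSV
#' @param passport passport data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_passport <- function(passport, path) {
  utils::write.csv(passport, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_passport <- function(pp) {
  need <- c("accession_id", "name", "aliases", "collection", "country",
            "region", "improvement_status", "cultivar_group")
  miss <- setdiff(need, names(pp))
  if (length(miss)) {
    stop("passport table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pp$accession_id)) {
    stop("passport accession_id values must be unique", call. = FALSE)
  }
  invisible(pp)
}

#' Apply genotype quality-control filters
#'
#' Filtering order: (1) drop samples with call rate <= `sample_cr_max_excl`;
#' (2) drop markers with call rate <= `marker_cr_max_excl`; (3) optionally
#' impute remaining missing genotypes (when `impute_seed` is given); (4) drop
#' markers with heterozygosity proportion >= `marker_het_min_excl`, then
#' samples with heterozygosity >= `sample_het_min_excl`.  All boundaries are
#' inclusive as written.  Call rate is the non-missing fraction;
#' heterozygosity is computed over non-missing calls.
#'
#' @param g a [genotype_matrix].
#' @param sample_cr_max_excl samples with call rate at or below this are
#'   removed (default 0.50).
#' @param marker_cr_max_excl markers with call rate at or below this are
#'   removed (default 0.80).
#' @param marker_het_min_excl markers with heterozygosity at or above this
#'   are removed (default 0.4).
#' @param sample_het_min_excl samples with heterozygosity at or above this
#'   are removed (default 0.2).
#' @param impute_seed if non-NULL, missing genotypes are imputed (see
#'   [impute_missing()]) between the call-rate and heterozygosity steps, so
#'   heterozygosity is assessed on complete data.
#' @return list with elements `genotypes` (filtered [genotype_matrix]) and
#'   `report` (a `qc_report`).
#' @export
apply_qc_filters <- function(g,
                             sample_cr_max_excl = 0.50,
                             marker_cr_max_excl = 0.80,
                             marker_het_min_excl = 0.4,
                             sample_het_min_excl = 0.2,
                             impute_seed = NULL) {
  steps <- list()
  n0 <- nrow(g$dosages); m0 <- ncol(g$dosages)

  cr <- call_rates(g)
  drop_s <- cr$sample <= sample_cr_max_excl
  steps$sample_call_rate <- data.frame(
    accession_id = g$accession_ids[drop_s],
    call_rate = unname(cr$sample[drop_s]))
  g <- subset_genotypes(g, samples = !drop_s)
  if (nrow(g$dosages) == 0) stop("all samples removed by call-rate filter",
                                 call. = FALSE)

  cr <- call_rates(g)
  drop_m <- cr$marker <= marker_cr_max_excl
  steps$marker_call_rate <- data.frame(
    marker = which(drop_m), call_rate = unname(cr$marker[drop_m]))
  g <- subset_genotypes(g, markers = !drop_m)

  if (!is.null(impute_seed)) {
    g <- impute_missing(g, seed = impute_seed)
  }

  ht <- het_rates(g)
  drop_m <- !is.nan(ht$marker) & ht$marker >= marker_het_min_excl
  steps$marker_het <- data.frame(
    marker = which(drop_m), het = unname(ht$marker[drop_m]))
  g <- subset_genotypes(g, markers = !drop_m)

  ht <- het_rates(g)
  drop_s <- !is.nan(ht$sample) & ht$sample >= sample_het_min_excl
  steps$sample_het <- data.frame(
    accession_id = g$accession_ids[drop_s], het = unname(ht$sample[drop_s]))
  g <- subset_genotypes(g, samples = !drop_s)
  if (nrow(g$dosages) == 0) stop("all samples removed by heterozygosity filter",
                                 call. = FALSE)

  report <- structure(list(
    steps = steps,
    n_samples_in = n0, n_markers_in = m0,
    n_samples_out = nrow(g$dosages), n_markers_out = ncol(g$dosages)
  ), class = "qc_report")
  stopifnot(report$n_samples_in - nrow(steps$sample_call_rate) -
              nrow(steps$sample_het) == report$n_samples_out,
            report$n_markers_in - nrow(steps$marker_call_rate) -
              nrow(steps$marker_het) == report$n_markers_out)
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples: %d -> %d (call rate -%d, heterozygosity -%d)\n",
              x$n_samples_in, x$n_samples_out,
              nrow(x$steps$sample_call_rate), nrow(x$steps$sample_het)))
  cat(sprintf("  markers: %d -> %d (call rate -%d, heterozygosity -%d)\n",
              x$n_markers_in, x$n_markers_out,
              nrow(x$steps$marker_call_rate), nrow(x$steps$marker_het)))
  invisible(x)
}

#' Impute missing genotypes by allele-frequency sampling
#'
#' Each missing genotype is filled by drawing two alleles from the marker's
#' observed ALT-allele frequency (a Binomial(2, p) dosage), i.e. imputation
#' under Hardy-Weinberg from marginal frequencies.  Non-missing calls are
#' never altered.  Markers with no observed calls are left missing and
#' flagged with a warning.
#'
#' @param g a [genotype_matrix].
#' @param seed integer seed; the fill is deterministic given the seed.
#' @return a [genotype_matrix] with missing entries filled.
#' @export
impute_missing <- function(g, seed = 1L) {
  d <- g$dosages
  p <- allele_freq(g)
  empty <- is.nan(p)
  if (any(empty)) {
    warning(sum(empty), " marker(s) fully missing; left unimputed")
  }
  rng <- local_rng(seed)
  for (j in which(!empty)) {
    miss <- is.na(d[, j])
    if (any(miss)) {
      d[miss, j] <- as.integer(rng$rbinom(sum(miss), 2, p[j]))
    }
  }
  genotype_matrix(d, g$markers, g$accession_ids)
}

# Isolated RNG helper: evaluates random draws under a private seed without
# disturbing the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  wrap <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(rbinom = wrap(stats::rbinom), runif = wrap(stats::runif),
       sample = wrap(base::sample), rbeta = wrap(stats::rbeta),
       rgamma = wrap(stats::rgamma), sample_int = wrap(base::sample.int))
}

#' Filter markers on minor allele frequency
#'
#' Retains markers with MAF at or above `maf_min` (boundary inclusive).
#' Frequencies are computed from non-missing calls.
#'
#' @param g a [genotype_matrix].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return a [genotype_matrix] with low-MAF markers removed.
#' @export
filter_maf <- function(g, maf_min = 0.01) {
  maf <- minor_allele_freq(g)
  keep <- !is.nan(maf) & maf >= maf_min
  subset_genotypes(g, markers = keep)
}

#' Prune markers in linkage disequilibrium
#'
#' Sliding-window LD pruning in the style of `--indep-pairwise`: windows of
#' `window` markers advanced by `step`; within each window, while any retained
#' pair has squared dosage correlation above `r2_max`, the pair member with
#' the lower MAF is removed (ties remove the higher marker index).  Windows
#' never span chromosome boundaries.
#'
#' @param g a [genotype_matrix].
#' @param window window size in markers (default 50).
#' @param step window increment in markers (default 5).
#' @param r2_max maximum tolerated squared correlation (default 0.5).
#' @return a [genotype_matrix] containing the retained markers, in their
#'   original order.
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_max = 0.5) {
  if (window < step) stop("window must be >= step", call. = FALSE)
  keep <- rep(TRUE, ncol(g$dosages))
  maf <- minor_allele_freq(g)
  d <- g$dosages
  for (ch in unique(g$markers$chrom)) {
    idx <- which(g$markers$chrom == ch)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win_keep <- win[keep[win]]
      if (length(win_keep) >= 2) {
        r2 <- suppressWarnings(
          stats::cor(d[, win_keep, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        repeat {
          r2sub <- r2
          diag(r2sub) <- 0
          r2sub[is.na(r2sub)] <- 0
          if (all(r2sub <= r2_max)) break
          hit <- which(r2sub > r2_max, arr.ind = TRUE)
          hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
          i <- win_keep[hit[1, 1]]; j <- win_keep[hit[1, 2]]
          drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
          keep[drop] <- FALSE
          at <- match(drop, win_keep)
          win_keep <- win_keep[-at]
          r2 <- r2[-at, -at, drop = FALSE]
          if (length(win_keep) < 2) break
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  subset_genotypes(g, markers = keep)
}

#' Principal component analysis of a genotype matrix
#'
#' Markers are mean-centered (missing values replaced by the marker mean)
#' and decomposed by SVD via [stats::prcomp()].
#'
#' @param g a [genotype_matrix].
#' @param n_components number of components to return; truncated with a
#'   warning when it exceeds the matrix rank.
#' @return list with `scores` (accessions x components), `explained`
#'   (variance fractions) and `sdev`.
#' @export
pca_genotypes <- function(g, n_components = 10) {
  if (nrow(g$dosages) < 2) stop("PCA needs at least 2 accessions", call. = FALSE)
  x <- g$dosages
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds rank (", rank, "); truncated")
    n_components <- rank
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       sdev = pc$sdev[seq_len(n_components)])
}
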