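#' Genotype matrix container
#'
#' Holds diploid biallelic SNP genotypes as ALT-allele dosages (0, 1, 2) with
#' `NA` as the missing sentinel, together with marker coordinates.  Rows are
#' accessions, columns are markers.
#'
#' @param dosages integer matrix (accessions x markers) with values in
#'   \{0, 1, 2, NA\}.  Row names are taken as accession IDs if `accession_ids`
#'   is not given.
#' @param markers data.frame with one row per marker and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`.  Positions must be strictly increasing
#'   within each chromosome.
#' @param accession_ids optional character vector of unique accession IDs.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `markers`, `accession_ids`.
#' @export
genotype_matrix <- function(dosages, markers, accession_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(accession_ids)) {
    accession_ids <- paste0("ACC", seq_len(nrow(dosages)))
  }
  accession_ids <- as.character(accession_ids)
  if (anyDuplicated(accession_ids)) {
    stop("accession IDs must be unique", call. = FALSE)
  }
  if (length(accession_ids) != nrow(dosages)) {
    stop("length(accession_ids) must equal nrow(dosages)", call. = FALSE)
  }
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  markers <- as.data.frame(markers)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (nrow(markers) != ncol(dosages)) {
    stop("nrow(markers) must equal ncol(dosages)", call. = FALSE)
  }
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome ",
           ch, call. = FALSE)
    }
  }
  rownames(dosages) <- accession_ids
  structure(
    list(dosages = dosages, markers = markers, accession_ids = accession_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by accessions and/or markers
#'
#' @param g a `genotype_matrix`.
#' @param samples logical/integer/character index of accessions to keep.
#' @param markers logical/integer index of markers to keep.
#' @return The subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  d <- g$dosages
  mk <- g$markers
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    mk <- mk[markers, , drop = FALSE]
    rownames(mk) <- NULL
  }
  genotype_matrix(d, mk)
}

#' Per-sample and per-marker call rates
#'
#' Call rate is the fraction of non-missing genotype calls.
#'
#' @param g a `genotype_matrix`.
#' @return list with numeric vectors `sample` (named by accession) and
#'   `marker`.
#' @export
call_rates <- function(g) {
  ok <- !is.na(g$dosages)
  list(sample = rowMeans(ok), marker = colMeans(ok))
}

#' Per-sample and per-marker heterozygosity proportions
#'
#' Heterozygosity is the fraction of non-missing calls that are heterozygous
#' (dosage 1).  Samples or markers with no non-missing calls get `NaN`.
#'
#' @param g a `genotype_matrix`.
#' @return list with numeric vectors `sample` and `marker`.
#' @export
het_rates <- function(g) {
  het <- g$dosages == 1L
  ok  <- !is.na(g$dosages)
  het[is.na(het)] <- FALSE
  list(sample = rowSums(het) / rowSums(ok),
       marker = colSums(het) / colSums(ok))
}

#' ALT allele frequencies per marker
#'
#' @param g a `genotype_matrix`.
#' @return numeric vector of ALT-allele frequencies (NaN where a marker has
#'   no non-missing calls).
#' @export
allele_freq <- function(g) {
  colMeans(g$dosages, na.rm = TRUE) / 2
}

#' Minor allele frequencies per marker
#'
#' @param g a `genotype_matrix`.
#' @return numeric vector, `pmin(p, 1 - p)` of the ALT frequency.
#' @export
minor_allele_freq <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}
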