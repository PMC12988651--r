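#' Kruskal-Wallis tests of group ancestry proportions across regions
#'
#' For each genetic group (column of Q), tests whether the distribution of
#' ancestry proportions differs among geographic regions, after removing
#' regions with fewer than `min_region` accessions.  Uses midranks for ties,
#' the tie-corrected H statistic and the chi-square approximation
#' (df = regions - 1), via [stats::kruskal.test()].
#'
#' @param q an `ancestry_result` or Q matrix (n x K).
#' @param regions character vector of per-accession region labels.
#' @param min_region minimum region size retained (default 10).
#' @return data.frame with columns `group`, `H`, `df`, `p_value`, plus
#'   attribute `regions_used`.
#' @export
kruskal_wallis_by_group <- function(q, regions, min_region = 10) {
  Q <- if (inherits(q, "ancestry_result")) q$Q else as.matrix(q)
  regions <- as.character(regions)
  stopifnot(length(regions) == nrow(Q))
  sizes <- table(regions)
  keep_regions <- names(sizes)[sizes >= min_region]
  if (length(keep_regions) < 2) {
    stop("need >= 2 regions with at least ", min_region, " accessions",
         call. = FALSE)
  }
  sel <- regions %in% keep_regions
  Qs <- Q[sel, , drop = FALSE]
  rg <- factor(regions[sel])
  out <- lapply(seq_len(ncol(Qs)), function(k) {
    v <- Qs[, k]
    if (length(unique(v)) == 1) {
      data.frame(group = paste0("group", k), H = 0,
                 df = nlevels(rg) - 1, p_value = 1)
    } else {
      kt <- stats::kruskal.test(v, rg)
      data.frame(group = paste0("group", k),
                 H = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value)
    }
  })
  out <- do.call(rbind, out)
  attr(out, "regions_used") <- keep_regions
  out
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction and compact
#' letters
#'
#' Two-sided rank-sum tests for every region pair (exact enumeration when
#' both sides have at most 8 observations and no ties; otherwise the normal
#' approximation with tie correction), Bonferroni-adjusted by the number of
#' region pairs.  Regions are summarised with a compact letter display over
#' the non-significance graph (insert-and-absorb algorithm): two regions share
#' a letter if and only if they are not significantly different.
#'
#' @param values numeric response (e.g. one group's ancestry proportions).
#' @param regions per-observation region labels.
#' @param alpha significance level for the letters (default 0.05).
#' @return list with `p_adjusted` (symmetric matrix), `letters` (named by
#'   region, ordered by decreasing mean), `means`.
#' @export
pairwise_wilcoxon_cld <- function(values, regions, alpha = 0.05) {
  regions <- as.character(regions)
  labs <- sort(unique(regions))
  r <- length(labs)
  if (r < 2) stop("need >= 2 regions", call. = FALSE)
  pm <- matrix(NA_real_, r, r, dimnames = list(labs, labs))
  n_pairs <- r * (r - 1) / 2
  for (i in seq_len(r)) for (j in seq_len(i - 1L)) {
    a <- values[regions == labs[i]]
    b <- values[regions == labs[j]]
    if (!length(a) || !length(b)) next
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    pm[i, j] <- pm[j, i] <- min(1, p * n_pairs)
  }
  means <- vapply(labs, function(l) mean(values[regions == l]), 0)
  sig <- !is.na(pm) & pm < alpha
  letters <- cld_insert_absorb(sig, order(means, decreasing = TRUE))
  list(p_adjusted = pm, letters = letters[order(means, decreasing = TRUE)],
       means = means)
}

# Compact letter display by insert-and-absorb over a significance matrix
# (TRUE = significantly different).  `ord` gives the display order (letters
# are grown along decreasing means, as in standard CLD output).
cld_insert_absorb <- function(sig, ord = seq_len(nrow(sig))) {
  r <- nrow(sig)
  labs <- rownames(sig)
  cols <- list(rep(TRUE, r))            # start: everyone shares one letter
  for (i in ord) for (j in ord) {
    if (j <= i || !sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] <= cols[[b]]) &&
          any(cols[[b]] & !cols[[a]])) {
        keep[a] <- FALSE
      } else if (a < b && keep[a] && keep[b] &&
                 identical(cols[[a]], cols[[b]])) {
        keep[b] <- FALSE
      }
    }
    cols <- cols[keep]
  }
  # order columns by first member along `ord`, assign letters
  first <- vapply(cols, function(col) match(TRUE, col[ord]), 0L)
  cols <- cols[order(first)]
  out <- vapply(seq_len(r), function(i) {
    paste0(letters[which(vapply(cols, function(col) col[i], TRUE))],
           collapse = "")
  }, "")
  names(out) <- labs
  out
}

#' Rarefaction-replicated geographic enrichment of genetic groups
#'
#' For each replicate, every eligible region (n >= `size`) is subsampled to
#' `size` accessions without replacement; per group, a Kruskal-Wallis test is
#' run and, when significant at `alpha`, Bonferroni-corrected pairwise
#' Wilcoxon tests follow.  A group is called *enriched* in a region when that
#' region has the highest mean ancestry proportion and differs significantly
#' from every other region.  Reported per (group, region): the mean rarefied
#' proportion and the fraction of replicates in which enrichment was called.
#'
#' @param q an `ancestry_result` or Q matrix.
#' @param regions per-accession region labels.
#' @param size rarefaction sample size per region (default 50).
#' @param reps number of replicates (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the subsampling.
#' @return an object of class `enrichment_result`: data.frame `summary`
#'   (group, region, mean_q, enriched_fraction), `full_data` (the same call
#'   on the unrarefied data: means, letters, enrichment flags, KW results),
#'   `regions_used`, `reps`, `size`.
#' @export
rarefied_enrichment <- function(q, regions, size = 50, reps = 500,
                                alpha = 0.05, seed = 1L) {
  Q <- if (inherits(q, "ancestry_result")) q$Q else as.matrix(q)
  regions <- as.character(regions)
  sizes <- table(regions)
  eligible <- names(sizes)[sizes >= size]
  if (length(eligible) < 2) {
    stop("need >= 2 regions with at least ", size, " accessions",
         call. = FALSE)
  }
  skipped <- setdiff(names(sizes), eligible)
  if (length(skipped)) {
    message("region(s) below rarefaction size excluded: ",
            paste(skipped, collapse = ", "))
  }
  K <- ncol(Q)
  rng <- local_rng(seed)
  enriched <- matrix(0, K, length(eligible),
                     dimnames = list(paste0("group", seq_len(K)), eligible))
  mean_q <- matrix(0, K, length(eligible), dimnames = dimnames(enriched))
  idx_of <- lapply(stats::setNames(eligible, eligible),
                   function(r) which(regions == r))
  for (b in seq_len(reps)) {
    take <- unlist(lapply(idx_of, function(ii) ii[rng$sample_int(length(ii), size)]),
                   use.names = FALSE)
    rg <- rep(eligible, each = size)
    for (k in seq_len(K)) {
      v <- Q[take, k]
      mu <- vapply(eligible, function(r) mean(v[rg == r]), 0)
      mean_q[k, ] <- mean_q[k, ] + mu
      if (length(unique(v)) == 1) next
      kw <- stats::kruskal.test(v, factor(rg))
      if (is.na(kw$p.value) || kw$p.value >= alpha) next
      pw <- pairwise_wilcoxon_cld(v, rg, alpha = alpha)
      top <- names(which.max(pw$means))
      others <- setdiff(eligible, top)
      pj <- pw$p_adjusted[top, others]
      if (all(!is.na(pj)) && all(pj < alpha)) {
        enriched[k, top] <- enriched[k, top] + 1
      }
    }
  }
  mean_q <- mean_q / reps
  frac <- enriched / reps

  # unrarefied reference analysis with compact letters
  kw_full <- kruskal_wallis_by_group(Q, regions,
                                     min_region = min(10, size))
  regs_full <- attr(kw_full, "regions_used")
  sel <- regions %in% regs_full
  full <- lapply(seq_len(K), function(k) {
    gate <- kw_full$p_value[k] < alpha
    pw <- pairwise_wilcoxon_cld(Q[sel, k], regions[sel], alpha = alpha)
    top <- names(which.max(pw$means))
    pj <- pw$p_adjusted[top, setdiff(regs_full, top)]
    enr <- gate && all(!is.na(pj)) && all(pj < alpha)
    list(group = paste0("group", k), means = pw$means,
         letters = pw$letters, enriched_region = if (enr) top else NA_character_,
         kw_p = kw_full$p_value[k])
  })

  summary <- data.frame(
    group = rep(rownames(frac), times = ncol(frac)),
    region = rep(colnames(frac), each = nrow(frac)),
    mean_q = as.vector(mean_q),
    enriched_fraction = as.vector(frac),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, full_data = full,
                 regions_used = eligible, reps = reps, size = size),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("rarefied enrichment: %d regions x %d groups, size %d, %d replicates\n",
              length(x$regions_used), length(x$full_data), x$size, x$reps))
  called <- x$summary[x$summary$enriched_fraction > 0.5, ]
  if (nrow(called)) {
    cat("  enriched (in >50% of replicates):\n")
    for (i in seq_len(nrow(called))) {
      cat(sprintf("    %s in %s (%.0f%% of replicates, mean Q %.3f)\n",
                  called$group[i], called$region[i],
                  100 * called$enriched_fraction[i], called$mean_q[i]))
    }
  } else cat("  no region enriched in a majority of replicates\n")
  invisible(x)
}
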