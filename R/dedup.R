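#' Thresholds for multi-criteria duplicate detection
#'
#' A pair is a potential duplicate when its Nei distance is at most `d_max`,
#' its genomic relationship at least `g_min` and its pi-hat at least
#' `pihat_min` (all boundaries inclusive).
#'
#' @param d_max maximum Nei distance (default 0.03).
#' @param g_min minimum GRM value (default 1.3).
#' @param pihat_min minimum pi-hat (default 0.6).
#' @return an object of class `duplicate_criteria`.
#' @export
duplicate_criteria <- function(d_max = 0.03, g_min = 1.3, pihat_min = 0.6) {
  stopifnot(d_max > 0, pihat_min > 0, pihat_min <= 1)
  structure(list(d_max = d_max, g_min = g_min, pihat_min = pihat_min),
            class = "duplicate_criteria")
}

#' Flag potential duplicate pairs
#'
#' @param pairs relatedness table from [pair_relatedness()] with columns
#'   `id1`, `id2`, `d`, `g`, `pi_hat`.
#' @param crit a [duplicate_criteria].
#' @return the subset of `pairs` meeting all three criteria.  Pairs with any
#'   missing metric are skipped (with a message).
#' @export
flag_potential_duplicates <- function(pairs, crit = duplicate_criteria()) {
  need <- c("d", "g", "pi_hat")
  ok <- stats::complete.cases(pairs[, need])
  if (any(!ok)) {
    message(sum(!ok), " pair(s) skipped: missing relatedness metric")
  }
  sel <- ok & pairs$d <= crit$d_max & pairs$g >= crit$g_min &
    pairs$pi_hat >= crit$pihat_min
  pairs[sel, , drop = FALSE]
}

#' Normalise an accession name for matching
#'
#' Uppercases and strips all whitespace and punctuation, so "TVu-1234 " and
#' "tvu 1234" collapse to the same canonical form.  An empty result is
#' returned as `NA` (no usable name, never matches).
#'
#' @param raw character vector of names.
#' @return character vector of canonical names, `NA` where no name survives.
#' @export
normalize_name <- function(raw) {
  out <- gsub("[^A-Z0-9]", "", toupper(as.character(raw)))
  out[is.na(raw) | out == ""] <- NA_character_
  out
}

# canonical name + alias set per accession
name_sets <- function(passport) {
  al <- strsplit(ifelse(is.na(passport$aliases), "", passport$aliases), ";")
  sets <- mapply(function(nm, a) {
    s <- normalize_name(c(nm, a))
    unique(s[!is.na(s)])
  }, passport$name, al, SIMPLIFY = FALSE)
  names(sets) <- passport$accession_id
  sets
}

#' Confirm potential duplicates by passport name matching
#'
#' A potential pair is confirmed when the canonical name/alias sets of its
#' two accessions intersect.  Accessions without any usable name are never
#' confirmed.
#'
#' @param potential pair table from [flag_potential_duplicates()].
#' @param passport passport data.frame.
#' @return the confirmed subset of `potential`.
#' @export
confirm_duplicates <- function(potential, passport) {
  sets <- name_sets(passport)
  absent <- setdiff(unique(c(potential$id1, potential$id2)), names(sets))
  if (length(absent)) {
    stop("accessions absent from passport: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  hit <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])) > 0,
                potential$id1, potential$id2)
  potential[as.logical(hit), , drop = FALSE]
}

#' Resolve which accessions to retain among confirmed duplicates
#'
#' Confirmed pairs define a graph over accessions; within each connected
#' component the accession with the highest pre-imputation call rate is
#' retained (ties broken by lexicographically smallest ID) and the rest are
#' removed.
#'
#' @param confirmed confirmed pair table (columns `id1`, `id2`).
#' @param g a [genotype_matrix] giving the accession universe and
#'   (pre-imputation) call rates.
#' @param potential optional potential pair table, used only for the
#'   within/between-collection tallies.
#' @param passport optional passport data.frame (needed for collection
#'   tallies).
#' @return an object of class `duplicate_report`: list with `components`
#'   (list of ID vectors), `retained`, `removed`, `confirmed_pairs`,
#'   `potential_pairs` and `collection_tally`.
#' @export
resolve_retention <- function(confirmed, g, potential = NULL, passport = NULL) {
  ids <- g$accession_ids
  cr <- call_rates(g)$sample
  comps <- list()
  retained <- ids
  removed <- character(0)
  if (nrow(confirmed) > 0) {
    gr <- igraph::graph_from_data_frame(confirmed[, c("id1", "id2")],
                                        directed = FALSE)
    cmp <- igraph::components(gr)
    comps <- split(names(cmp$membership), cmp$membership)
    comps <- lapply(comps, sort)
    keep_of <- vapply(comps, function(members) {
      r <- cr[members]
      best <- members[r == max(r)]
      sort(best)[1]
    }, "")
    drop <- setdiff(unlist(comps), keep_of)
    removed <- sort(drop)
    retained <- setdiff(ids, removed)
  }
  tally <- NULL
  if (!is.null(passport)) {
    coll <- stats::setNames(passport$collection, passport$accession_id)
    wb <- function(p) {
      if (is.null(p) || nrow(p) == 0) return(c(within = NA_real_, between = NA_real_))
      w <- coll[p$id1] == coll[p$id2]
      c(within = 100 * mean(w), between = 100 * mean(!w))
    }
    tally <- rbind(potential = wb(potential), confirmed = wb(confirmed))
  }
  stopifnot(length(retained) + length(removed) == length(ids))
  structure(list(components = comps,
                 retained = retained,
                 removed = removed,
                 confirmed_pairs = confirmed,
                 potential_pairs = potential,
                 collection_tally = tally),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat("duplicate report\n")
  if (!is.null(x$potential_pairs))
    cat("  potential pairs:", nrow(x$potential_pairs), "\n")
  cat("  confirmed pairs:", nrow(x$confirmed_pairs), "\n")
  cat("  components:", length(x$components),
      " removed:", length(x$removed),
      " retained:", length(x$retained), "\n")
  if (!is.null(x$collection_tally)) {
    cat("  within/between-collection % (potential): ",
        sprintf("%.1f / %.1f", x$collection_tally["potential", "within"],
                x$collection_tally["potential", "between"]), "\n")
    cat("  within/between-collection % (confirmed): ",
        sprintf("%.1f / %.1f", x$collection_tally["confirmed", "within"],
                x$collection_tally["confirmed", "between"]), "\n")
  }
  invisible(x)
}

#' Number of unordered accession pairs
#'
#' Bookkeeping helper: `n * (n - 1) / 2` unique pairs (and `n * (n - 1)`
#' ordered pairs) among `n` accessions.
#'
#' @param n number of accessions.
#' @param ordered if TRUE, count ordered pairs.
#' @return pair count as a double (exact for n well beyond 1e5).
#' @export
pair_count <- function(n, ordered = FALSE) {
  n <- as.numeric(n)
  if (ordered) n * (n - 1) else n * (n - 1) / 2
}
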