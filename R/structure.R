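# Euclidean projection of each row of M onto the probability simplex
# (Duchi et al. 2008, sort-based), vectorised over rows.
proj_simplex_rows <- function(M) {
  n <- nrow(M); k <- ncol(M)
  if (k == 1) return(matrix(1, n, 1))
  S <- matrix(M[order(row(M), -M)], n, k, byrow = TRUE)  # rows sorted desc
  cs <- S
  for (j in 2:k) cs[, j] <- cs[, j - 1] + S[, j]
  jj <- matrix(rep(seq_len(k), each = n), n, k)
  cond <- S - (cs - 1) / jj > 0
  rho <- rowSums(cond)
  theta <- (cs[cbind(seq_len(n), rho)] - 1) / rho
  out <- M - theta
  out[out < 0] <- 0
  out
}

# One-hot genotype encoding: n x 3L matrix with per-locus blocks
# (P(g=0), P(g=1), P(g=2)).  Entries listed in `mask` (2-column matrix of
# (accession, locus)) are replaced by the locus' mean genotype distribution,
# computed from unmasked entries, so they carry no individual information.
encode_genotypes <- function(g, mask = NULL) {
  x <- g$dosages
  if (anyNA(x)) stop("complete (imputed) dosages required", call. = FALSE)
  n <- nrow(x); L <- ncol(x)
  Y <- matrix(0, n, 3L * L)
  for (s in 0:2) {
    Y[, seq(s + 1L, 3L * L, by = 3L)] <- (x == s) * 1
  }
  if (!is.null(mask) && nrow(mask)) {
    masked_by_locus <- split(mask[, 1], mask[, 2])
    for (lc in names(masked_by_locus)) {
      l <- as.integer(lc)
      rows <- masked_by_locus[[lc]]
      cols <- 3L * (l - 1L) + 1:3
      other <- setdiff(seq_len(n), rows)
      mgd <- if (length(other)) colMeans(Y[other, cols, drop = FALSE])
             else rep(1 / 3, 3)
      Y[rows, cols] <- matrix(mgd, length(rows), 3, byrow = TRUE)
    }
  }
  Y
}

#' Estimate individual ancestry coefficients by nonnegative matrix
#' factorisation
#'
#' Genotypes are one-hot encoded to an n x 3L indicator matrix Y and
#' factorised as Y ~ Q F, where the rows of Q (admixture coefficients, n x K)
#' and each per-locus 3-block of F (ancestral genotype frequencies) are
#' constrained to the probability simplex.  Q and F are updated by
#' alternating ridge-regularised least squares followed by Euclidean simplex
#' projection; a backtracking step toward the previous iterate (the simplex is
#' convex, so convex combinations stay feasible) guarantees a non-increasing
#' loss.  The best of `restarts` random initialisations is returned.
#'
#' @param g a [genotype_matrix] with complete (imputed) dosages.
#' @param K number of ancestral populations (>= 1).
#' @param seed integer seed; restarts use `seed`, `seed + 1`, ...
#' @param restarts number of random initialisations (default 5).
#' @param alpha ridge penalty on Q (default 0; small positive values sparsify
#'   against near-singular F blocks).
#' @param max_iter maximum iterations (default 200).
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @return an object of class `ancestry_result`: list with `Q` (n x K,
#'   rows sum to 1), `G_freq` (K x 3L ancestral genotype frequencies),
#'   `loss_trace` (non-increasing), `loss`, `K`, `seed`, `restarts`,
#'   `converged`.
#' @export
estimate_ancestry <- function(g, K, seed = 1L, restarts = 5, alpha = 0,
                              max_iter = 200, tol = 1e-6) {
  n <- nrow(g$dosages)
  if (K > n) stop("K cannot exceed the number of accessions", call. = FALSE)
  Y <- encode_genotypes(g)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- nmf_ancestry_fit(Y, K, seed = seed + r - 1L, alpha = alpha,
                            max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  if (!best$converged) {
    warning("ancestry estimation did not converge; best iterate returned")
  }
  dimnames(best$Q) <- list(g$accession_ids, paste0("Q", seq_len(K)))
  structure(c(best, list(K = K, seed = seed, restarts = restarts)),
            class = "ancestry_result")
}

nmf_ancestry_fit <- function(Y, K, seed, alpha = 0, max_iter = 200,
                             tol = 1e-6) {
  n <- nrow(Y); L3 <- ncol(Y)
  rng <- local_rng(seed)
  Q <- matrix(rng$rgamma(n * K, shape = 1), n, K)
  Q <- Q / rowSums(Q)
  Fm <- update_F(Q, Y, L3)
  loss_of <- function(Q, Fm) {
    R <- Y - Q %*% Fm
    sum(R * R) + alpha * sum(Q * Q)
  }
  loss <- loss_of(Q, Fm)
  trace <- loss
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Fn <- update_F(Q, Y, L3)
    Qn <- update_Q(Fn, Y, alpha)
    new_loss <- loss_of(Qn, Fn)
    if (new_loss > loss) {
      # backtrack toward the previous (feasible) iterate
      ok <- FALSE
      th <- 0.5
      for (b in 1:8) {
        Qc <- th * Qn + (1 - th) * Q
        Fc <- th * Fn + (1 - th) * Fm
        cl <- loss_of(Qc, Fc)
        if (cl <= loss) { Qn <- Qc; Fn <- Fc; new_loss <- cl; ok <- TRUE; break }
        th <- th / 2
      }
      if (!ok) { converged <- TRUE; break }
    }
    rel <- (loss - new_loss) / max(loss, .Machine$double.eps)
    Q <- Qn; Fm <- Fn; loss <- new_loss
    trace <- c(trace, loss)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(Q = Q, G_freq = Fm, loss_trace = trace, loss = loss,
       converged = converged)
}

update_F <- function(Q, Y, L3) {
  K <- ncol(Q)
  A <- crossprod(Q) + diag(1e-10, K)
  Fm <- solve(A, crossprod(Q, Y))
  # project each per-locus 3-block of each ancestral row onto the simplex
  L <- L3 / 3L
  blk <- matrix(t(Fm), ncol = 3, byrow = TRUE)   # (K*L) x 3, loci fastest
  blk <- proj_simplex_rows(blk)
  t(matrix(t(blk), nrow = L3))
}

update_Q <- function(Fm, Y, alpha) {
  K <- nrow(Fm)
  B <- tcrossprod(Fm) + diag(alpha + 1e-10, K)
  Q <- t(solve(B, Fm %*% t(Y)))
  proj_simplex_rows(Q)
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry_result: n = %d, K = %d, loss = %.4g (%d iterations)\n",
              nrow(x$Q), x$K, x$loss, length(x$loss_trace)))
  invisible(x)
}

#' Select K by masked cross-entropy
#'
#' For each replicate, a random fraction of genotype entries is masked
#' (replaced by the locus mean genotype distribution in the one-hot
#' encoding), the ancestry model is fitted, and the cross-entropy of the
#' predicted genotype probabilities on the masked entries is recorded.  The
#' suggested K is the elbow of the mean cross-entropy curve (maximum second
#' difference); the K with minimum mean cross-entropy is also reported.
#'
#' @param g a [genotype_matrix] with complete dosages.
#' @param K_range contiguous integer range of K values (default 1:10).
#' @param mask_frac fraction of entries masked per replicate, in (0, 0.5)
#'   (default 0.05).
#' @param reps replicates per K (default 20).
#' @param seed integer seed.
#' @param restarts restarts per fit (default 1; replicates already vary the
#'   initialisation).
#' @param ... passed to the fitter (e.g. `max_iter`, `alpha`).
#' @return an object of class `k_selection`: data.frame `summary` (K, mean,
#'   sd, second difference), matrix `cross_entropy` (reps x K), `k_elbow`,
#'   `k_min`.
#' @export
select_k_cross_entropy <- function(g, K_range = 1:10, mask_frac = 0.05,
                                   reps = 20, seed = 1L, restarts = 1, ...) {
  stopifnot(mask_frac > 0, mask_frac < 0.5, all(diff(K_range) == 1))
  n <- nrow(g$dosages); L <- ncol(g$dosages)
  n_mask <- round(mask_frac * n * L)
  if (n_mask < 1) stop("mask_frac masks no entries", call. = FALSE)
  x <- g$dosages
  if (anyNA(x)) stop("complete (imputed) dosages required", call. = FALSE)
  rng <- local_rng(seed)
  ce <- matrix(NA_real_, reps, length(K_range),
               dimnames = list(NULL, paste0("K", K_range)))
  for (r in seq_len(reps)) {
    sel <- rng$sample_int(n * L, n_mask)
    mask <- cbind(((sel - 1) %% n) + 1L, ((sel - 1) %/% n) + 1L)
    Ym <- encode_genotypes(g, mask = mask)
    obs <- x[mask]
    for (ki in seq_along(K_range)) {
      K <- K_range[ki]
      best <- NULL
      for (s in seq_len(restarts)) {
        fit <- nmf_ancestry_fit(Ym, K, seed = seed + 1000L * r + s, ...)
        if (is.null(best) || fit$loss < best$loss) best <- fit
      }
      P <- best$Q %*% best$G_freq
      cols <- 3L * (mask[, 2] - 1L) + obs + 1L
      p_obs <- P[cbind(mask[, 1], cols)]
      # renormalise the predicted 3-block and floor away log(0)
      tot <- P[cbind(mask[, 1], 3L * (mask[, 2] - 1L) + 1L)] +
        P[cbind(mask[, 1], 3L * (mask[, 2] - 1L) + 2L)] +
        P[cbind(mask[, 1], 3L * (mask[, 2] - 1L) + 3L)]
      p_obs <- pmax(p_obs / pmax(tot, .Machine$double.eps), 1e-12)
      ce[r, ki] <- -mean(log(p_obs))
    }
  }
  mu <- colMeans(ce)
  sdv <- apply(ce, 2, stats::sd)
  d2 <- rep(NA_real_, length(K_range))
  if (length(K_range) >= 3) {
    for (i in 2:(length(K_range) - 1)) {
      d2[i] <- mu[i - 1] - 2 * mu[i] + mu[i + 1]
    }
  }
  k_elbow <- if (all(is.na(d2))) K_range[which.min(mu)]
             else K_range[which.max(d2)]
  structure(list(
    summary = data.frame(K = K_range, mean_ce = mu, sd_ce = sdv,
                         second_diff = d2, row.names = NULL),
    cross_entropy = ce,
    k_elbow = k_elbow,
    k_min = K_range[which.min(mu)]
  ), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("cross-entropy K selection: elbow K =", x$k_elbow,
      "; minimum-CE K =", x$k_min, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Evanno delta-K from replicate objective values
#'
#' delta-K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' defined for interior K with positive replicate spread.
#'
#' @param replicate_losses named list (names = contiguous K values, length
#'   >= 3) of numeric vectors of per-replicate objective values (>= 2
#'   replicates each).
#' @return data.frame with columns `K`, `mean`, `sd`, `delta_k` (NA at the
#'   range ends and where sd = 0), plus attribute `k_best` (K maximising
#'   delta-K).
#' @export
evanno_delta_k <- function(replicate_losses) {
  ks <- as.integer(names(replicate_losses))
  if (length(ks) < 3 || any(diff(ks) != 1)) {
    stop("need a contiguous K range of length >= 3", call. = FALSE)
  }
  if (any(vapply(replicate_losses, length, 1L) < 2)) {
    stop("need >= 2 replicates per K", call. = FALSE)
  }
  mu <- vapply(replicate_losses, mean, 0)
  sdv <- vapply(replicate_losses, stats::sd, 0)
  dk <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1)) {
    if (sdv[i] > 0) {
      dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
    }
  }
  out <- data.frame(K = ks, mean = mu, sd = sdv, delta_k = dk,
                    row.names = NULL)
  attr(out, "k_best") <- if (all(is.na(dk))) NA_integer_
                         else ks[which.max(dk)]
  out
}

#' Assign accessions to genetic groups at a membership threshold
#'
#' An accession is assigned to its maximum-Q group when that maximum is at
#' least `threshold` (inclusive); otherwise it is labelled `"admixed"`.
#' Argmax ties break to the lowest group index.
#'
#' @param q an `ancestry_result` or a numeric Q matrix (rows sum to 1).
#' @param threshold membership threshold (default 0.70).
#' @return character vector of labels `"group1"`, ..., `"groupK"` or
#'   `"admixed"`, named by accession where Q has rownames.
#' @export
assign_groups <- function(q, threshold = 0.70) {
  Q <- if (inherits(q, "ancestry_result")) q$Q else as.matrix(q)
  k <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), k)]
  out <- ifelse(mx >= threshold, paste0("group", k), "admixed")
  names(out) <- rownames(Q)
  out
}

#' Align the columns of an estimated Q matrix to a reference
#'
#' Searches all column permutations (label switching) for the one minimising
#' the root-mean-square error against the reference, and returns the permuted
#' matrix.  Intended for validation against known admixture proportions.
#'
#' @param q_est estimated Q matrix (n x K).
#' @param q_ref reference Q matrix (n x K).
#' @return list with `Q` (permuted estimate), `perm` and `rmse`.
#' @export
align_q_columns <- function(q_est, q_ref) {
  K <- ncol(q_est)
  stopifnot(ncol(q_ref) == K, nrow(q_ref) == nrow(q_est))
  perms <- all_permutations(K)
  best <- NULL
  for (p in perms) {
    r <- sqrt(mean((q_est[, p, drop = FALSE] - q_ref)^2))
    if (is.null(best) || r < best$rmse) best <- list(perm = p, rmse = r)
  }
  list(Q = q_est[, best$perm, drop = FALSE], perm = best$perm,
       rmse = best$rmse)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
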