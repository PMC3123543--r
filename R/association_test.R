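#' Reduced-model fit and residuals for one (mRNA, miRNA) pair
#'
#' Fits PLS of a single mRNA on all miRNAs except column `j`. The residuals
#' of this reduced model estimate the error under the null hypothesis that
#' miRNA `j` has no association with the mRNA, and seed the residual
#' bootstrap.
#'
#' @param X Samples x miRNAs matrix on the original (log2) scale, `p >= 2`.
#' @param Y_i Numeric response vector (one mRNA), length `nrow(X)`.
#' @param j Index of the miRNA column to leave out.
#' @param ncomp Number of latent components for the reduced fit; must
#'   satisfy `ncomp <= min(n - 1, p - 1)`.
#' @return List with `fitted_reduced` and `residuals` (both length n).
#' @export
reduced_model_residuals <- function(X, Y_i, j, ncomp = 3L) {
  if (!is.matrix(X)) stopf("'X' must be a matrix")
  p <- ncol(X)
  if (p < 2L) stopf("no reduced model exists with a single miRNA (p = 1)")
  j <- as.integer(j)
  if (j < 1L || j > p) stopf("'j' out of range")
  if (ncomp > min(nrow(X) - 1L, p - 1L)) {
    stopf("'ncomp' too large for the reduced design (max %d)",
          min(nrow(X) - 1L, p - 1L))
  }
  Xr <- standardize(X[, -j, drop = FALSE])
  my <- mean(Y_i); sdy <- stats::sd(Y_i)
  if (sdy == 0) stopf("response has zero variance")
  coef_std <- pls1_coef_std(Xr$values, (Y_i - my) / sdy, ncomp)
  fitted <- my + sdy * drop(Xr$values %*% coef_std)
  list(fitted_reduced = fitted, residuals = Y_i - fitted)
}

# Original-scale beta of miRNA j from a full single-response PLS fit of y on
# X (standardized design precomputed by the caller). Degenerate y (zero sd,
# possible when bootstrap residuals are all equal) yields beta = 0.
beta_full_single <- function(Xs, y, j, ncomp) {
  my <- mean(y); sdy <- stats::sd(y)
  if (sdy == 0) return(0)
  coef_std <- pls1_coef_std(Xs$values, (y - my) / sdy, ncomp)
  if (j > length(coef_std)) return(0)
  coef_std[j] * sdy / Xs$sds[j]
}

#' Residual-bootstrap null distribution of one association score
#'
#' Implements the leave-one-miRNA-out residual bootstrap: residuals of the
#' reduced model (without miRNA `j`) are resampled with replacement, added
#' back onto the reduced-model fit to form bootstrap responses `Y*`, and the
#' full-model PLS score `beta*_ij` is recorded for each replicate. The
#' resulting sample is the null distribution of `beta_ij` under
#' `H0: beta_ij = 0`.
#'
#' @inheritParams reduced_model_residuals
#' @param B Number of bootstrap replicates (default 1000).
#' @param rng_seed Integer seed; the output is fully determined by it.
#' @return Numeric vector of `B` bootstrap scores `beta*_ij` on the
#'   original scale.
#' @export
bootstrap_association_null <- function(X, Y_i, j, B = 1000L, ncomp = 3L,
                                       rng_seed = 1L) {
  B <- as.integer(B)
  if (B < 1L) stopf("'B' must be at least 1")
  red <- reduced_model_residuals(X, Y_i, j, ncomp = ncomp)
  Xs <- standardize(X)
  n <- nrow(X)
  idx <- with_seed(rng_seed,
                   matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
  vapply(seq_len(B), function(b) {
    ystar <- red$fitted_reduced + red$residuals[idx[b, ]]
    beta_full_single(Xs, ystar, j, ncomp)
  }, numeric(1))
}

#' One-sided bootstrap p-value for a negative association
#'
#' Left-tail estimator with add-one correction:
#' `p = (1 + #[beta* <= beta_obs]) / (B + 1)`, testing
#' `H0: beta_ij = 0` against `Ha: beta_ij < 0`. The correction keeps p in
#' `(0, 1]`, so a finite bootstrap never reports p = 0.
#'
#' @param beta_observed Observed full-model score.
#' @param beta_null_samples Bootstrap null sample from
#'   [bootstrap_association_null()].
#' @return The p-value.
#' @export
bootstrap_pvalue <- function(beta_observed, beta_null_samples) {
  if (length(beta_null_samples) == 0L) stopf("empty bootstrap sample")
  (1 + sum(beta_null_samples <= beta_observed)) /
    (length(beta_null_samples) + 1)
}

#' Run the PLS + bootstrap target-prediction stage
#'
#' The core inference step: compute the per-mRNA PLS association scores of
#' the up-regulated mRNA block on the down-regulated miRNA block
#' ([pls_association_scores()]), bootstrap every (mRNA, miRNA) score's null
#' distribution, convert to one-sided p-values
#' (negative direction), apply Benjamini-Hochberg jointly across all
#' `m x p` pairs, and return the pairs with `q <= fdr_threshold` and
#' `beta < 0`. Per-pair RNG substreams are derived from
#' `(rng_seed, i, j)`, so results are independent of iteration order.
#'
#' @param data A `PairedDataset` with log2 blocks.
#' @param down_mirnas Character vector of miRNA IDs (predictors).
#' @param up_mrnas Character vector of mRNA IDs (responses).
#' @param ncomp Latent components for every PLS fit (default 3).
#' @param B Bootstrap replicates per pair (default 1000).
#' @param fdr_threshold q-value cutoff for the significant set (default 0.3).
#' @param rng_seed Master seed.
#' @param keep_null_samples If `TRUE`, attach the B bootstrap scores of every
#'   pair (memory-heavy at full scale; default `FALSE`).
#' @return List with `associations` (`AssociationMatrix`), `tests` (data
#'   frame: `mrna_id`, `mirna_id`, `beta_observed`, `p_value`, `q_value`,
#'   `significant`), `significant_pairs` (a `SignificantPairSet` data frame),
#'   and optionally `null_samples`.
#' @export
run_target_prediction <- function(data, down_mirnas, up_mrnas, ncomp = 3L,
                                  B = 1000L, fdr_threshold = 0.3,
                                  rng_seed = 1L, keep_null_samples = FALSE) {
  stopifnot(inherits(data, "PairedDataset"))
  if (length(down_mirnas) == 0L || length(up_mrnas) == 0L) {
    stopf("'down_mirnas' and 'up_mrnas' must be non-empty")
  }
  miss <- setdiff(down_mirnas, rownames(data$mirna$values))
  if (length(miss)) stopf("unknown miRNA ID: '%s'", miss[1L])
  miss <- setdiff(up_mrnas, rownames(data$mrna$values))
  if (length(miss)) stopf("unknown mRNA ID: '%s'", miss[1L])
  B <- as.integer(B)
  if (B < 1L) stopf("'B' must be at least 1")

  X <- t(data$mirna$values[down_mirnas, , drop = FALSE])
  Y <- t(data$mrna$values[up_mrnas, , drop = FALSE])
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)

  assoc <- association_scores_pls1(X, Y, ncomp = ncomp)
  Xs_full <- standardize(X)
  # one standardized leave-one-out design per miRNA, shared across mRNAs
  Xs_red <- lapply(seq_len(p), function(j) standardize(X[, -j, drop = FALSE]))

  pairs <- expand.grid(i = seq_len(m), j = seq_len(p))
  null_store <- if (keep_null_samples) vector("list", nrow(pairs)) else NULL
  pvals <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    y <- Y[, i]
    my <- mean(y); sdy <- stats::sd(y)
    coef_red <- pls1_coef_std(Xs_red[[j]]$values, (y - my) / sdy, ncomp)
    fitted <- my + sdy * drop(Xs_red[[j]]$values %*% coef_red)
    resid <- y - fitted
    idx <- with_seed(pair_seed(rng_seed, i, j),
                     matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
    beta_null <- vapply(seq_len(B), function(b) {
      beta_full_single(Xs_full, fitted + resid[idx[b, ]], j, ncomp)
    }, numeric(1))
    pvals[k] <- bootstrap_pvalue(assoc$beta[i, j], beta_null)
    if (keep_null_samples) null_store[[k]] <- beta_null
  }
  qvals <- benjamini_hochberg(pvals)
  tests <- data.frame(
    mrna_id = up_mrnas[pairs$i],
    mirna_id = down_mirnas[pairs$j],
    beta_observed = assoc$beta[cbind(pairs$i, pairs$j)],
    p_value = pvals,
    q_value = qvals,
    stringsAsFactors = FALSE
  )
  tests$significant <- tests$q_value <= fdr_threshold & tests$beta_observed < 0
  sig <- tests[tests$significant,
               c("mirna_id", "mrna_id", "beta_observed", "q_value")]
  names(sig)[3L] <- "beta"
  rownames(sig) <- NULL
  sig <- structure(sig, class = c("SignificantPairSet", "data.frame"),
                   fdr_threshold = fdr_threshold)
  out <- list(associations = assoc, tests = tests, significant_pairs = sig)
  if (keep_null_samples) out$null_samples <- null_store
  out
}

#' Per-miRNA target lists from a significant pair set
#'
#' @param pairs A `SignificantPairSet` (or any data frame with `mirna_id`
#'   and `mrna_id` columns).
#' @return Data frame with `mirna_id`, `n_targets`, `targets`
#'   (comma-joined, sorted gene IDs).
#' @export
targets_by_mirna <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(mirna_id = character(0), n_targets = integer(0),
                      targets = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(pairs$mrna_id, pairs$mirna_id)
  data.frame(
    mirna_id = names(sp),
    n_targets = vapply(sp, length, integer(1)),
    targets = vapply(sp, function(g) paste(sort(unique(g)), collapse = ","),
                     character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
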