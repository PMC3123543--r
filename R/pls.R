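#' Column-standardize a data block
#'
#' Centers and scales every column to mean 0, sd 1 (divisor `n - 1`),
#' keeping the means and sds so the transform is exactly invertible.
#'
#' @param block Numeric matrix, samples in rows, variables in columns.
#' @return A `StandardizedBlock`: list with `values`, `means`, `sds`.
#' @export
standardize <- function(block) {
  if (!is.matrix(block) || !is.numeric(block)) stopf("'block' must be a numeric matrix")
  means <- colMeans(block)
  sds <- apply(block, 2L, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    nm <- colnames(block)[zero[1L]] %||% as.character(zero[1L])
    stopf("zero-variance column: '%s' (filter constant genes upstream)", nm)
  }
  values <- sweep(sweep(block, 2L, means, "-"), 2L, sds, "/")
  structure(list(values = values, means = means, sds = sds),
            class = "StandardizedBlock")
}

as_standardized <- function(x) {
  if (inherits(x, "StandardizedBlock")) x else standardize(x)
}

# One NIPALS PLS1 pass: standardized X (n x p), centered/scaled y (n).
# Returns the p-vector of standardized regression coefficients. Kept lean:
# this is the bootstrap's inner loop.
pls1_coef_std <- function(Xs, ys, ncomp) {
  p <- ncol(Xs)
  E <- Xs
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(Xs), ncomp)
  for (k in seq_len(ncomp)) {
    w <- crossprod(E, ys)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) {  # X exhausted or y orthogonal to the residual space
      W <- W[, seq_len(k - 1L), drop = FALSE]
      P <- P[, seq_len(k - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(k - 1L), drop = FALSE]
      break
    }
    w <- w / nw
    tk <- E %*% w
    tt <- sum(tk * tk)
    pk <- crossprod(E, tk) / tt
    E <- E - tcrossprod(tk, pk)
    W[, k] <- w
    P[, k] <- pk
    Tm[, k] <- tk
  }
  if (ncol(W) == 0L) return(numeric(p))
  c_ols <- solve(crossprod(Tm), crossprod(Tm, ys))
  drop(W %*% solve(crossprod(P, W), c_ols))
}

nipals_fit <- function(Xs, Ys, ncomp, tol = 1e-10, max_iter = 500L) {
  n <- nrow(Xs); p <- ncol(Xs); m <- ncol(Ys)
  E <- Xs; F_ <- Ys
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  for (k in seq_len(ncomp)) {
    u <- F_[, which.max(apply(F_, 2L, function(c) sum(c * c)))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w * w))
      if (nw < 1e-12) stopf("NIPALS: X block exhausted at component %d", k)
      w <- w / nw
      tk <- E %*% w
      qk <- crossprod(F_, tk) / c(crossprod(tk))
      u <- F_ %*% qk / c(crossprod(qk))
      if (sqrt(sum((tk - t_old)^2)) < tol * sqrt(sum(tk * tk))) break
      t_old <- tk
    }
    tt <- c(crossprod(tk))
    pk <- crossprod(E, tk) / tt
    E <- E - tcrossprod(tk, pk)
    F_ <- F_ - tcrossprod(tk, crossprod(F_, tk) / tt)
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk
  }
  list(W = W, P = P, scores = Tm)
}

simpls_fit <- function(Xs, Ys, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  S <- crossprod(Xs, Ys)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); V <- matrix(0, p, ncomp)
  for (k in seq_len(ncomp)) {
    q <- svd(S, nu = 0, nv = 1)$v[, 1L]
    r <- S %*% q
    tk <- Xs %*% r
    nt <- sqrt(c(crossprod(tk)))
    if (nt < 1e-12) stopf("SIMPLS: X block exhausted at component %d", k)
    tk <- tk / nt; r <- r / nt
    pk <- crossprod(Xs, tk)
    v <- pk
    if (k > 1L) {
      Vk <- V[, seq_len(k - 1L), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pk)
    }
    v <- v / sqrt(c(crossprod(v)))
    S <- S - v %*% crossprod(v, S)
    R[, k] <- r; P[, k] <- pk; Tm[, k] <- tk; V[, k] <- v
  }
  list(W = R, P = P, scores = Tm)
}

#' Fit multi-response PLS regression
#'
#' Regresses a (standardized) mRNA block on a (standardized) miRNA block
#' through `ncomp` orthogonal latent variables. Latent scores are linear
#' combinations of the predictors; the response coefficients are obtained
#' by ordinary least squares of the responses on the full score matrix, and
#' mapped back to predictor-scale standardized coefficients.
#'
#' @param X Predictor block (miRNAs): `StandardizedBlock` or a plain
#'   samples x predictors matrix (standardized internally).
#' @param Y Response block (mRNAs): `StandardizedBlock` or plain matrix; a
#'   vector is treated as a single response.
#' @param ncomp Number of latent components `l` (default 3); must satisfy
#'   `l <= min(n - 1, p)`.
#' @param algorithm `"nipals"` (default) or `"simpls"`.
#' @return A `PLSFit`: list with `scores` (n x l), `x_weights`,
#'   `x_loadings`, `y_loadings`, `coef_std` (p x m standardized
#'   coefficients), `ncomp`, `algorithm`, and the `x_stats`/`y_stats`
#'   standardization parameters.
#' @export
fit_pls <- function(X, Y, ncomp = 3L, algorithm = c("nipals", "simpls")) {
  algorithm <- match.arg(algorithm)
  if (is.numeric(Y) && is.null(dim(Y)) && !inherits(Y, "StandardizedBlock")) {
    Y <- matrix(Y, ncol = 1L, dimnames = list(NULL, "y"))
  }
  X <- as_standardized(X)
  Y <- as_standardized(Y)
  n <- nrow(X$values); p <- ncol(X$values)
  if (nrow(Y$values) != n) stopf("X and Y must have the same number of samples")
  if (n < 3L) stopf("need at least 3 samples")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    stopf("'ncomp' must lie in [1, min(n - 1, p)] = [1, %d]", min(n - 1L, p))
  }
  core <- if (algorithm == "nipals") nipals_fit(X$values, Y$values, ncomp)
          else simpls_fit(X$values, Y$values, ncomp)
  Tm <- core$scores
  c_ols <- solve(crossprod(Tm), crossprod(Tm, Y$values))  # OLS on scores
  coef_std <- core$W %*% solve(crossprod(core$P, core$W), c_ols)
  dimnames(coef_std) <- list(colnames(X$values), colnames(Y$values))
  structure(list(
    ncomp = ncomp, algorithm = algorithm,
    x_weights = core$W, x_loadings = core$P, y_loadings = t(c_ols),
    scores = Tm, coef_std = coef_std,
    x_stats = list(means = X$means, sds = X$sds),
    y_stats = list(means = Y$means, sds = Y$sds)
  ), class = "PLSFit")
}

#' Back-transform standardized PLS coefficients to the original scale
#'
#' The original-scale association score linking miRNA `j` to mRNA `i` is
#' `beta[i, j] = coef_std[j, i] * sd_Y_i / sd_X_j`, with intercept
#' `beta0[i] = mean_Y_i - sum_j beta[i, j] * mean_X_j`. Negative scores
#' indicate the inverse association the method seeks.
#'
#' @param fit A `PLSFit`.
#' @return An `AssociationMatrix`: list with `beta` (m x p), `intercepts`
#'   (length m), `mirna_ids`, `mrna_ids`.
#' @export
back_transform_coefficients <- function(fit) {
  stopifnot(inherits(fit, "PLSFit"))
  sd_x <- fit$x_stats$sds; sd_y <- fit$y_stats$sds
  beta <- t(fit$coef_std) * outer(sd_y, 1 / sd_x)  # m x p
  intercepts <- fit$y_stats$means - as.vector(beta %*% fit$x_stats$means)
  mirna_ids <- rownames(fit$coef_std) %||% paste0("x", seq_len(ncol(beta)))
  mrna_ids <- colnames(fit$coef_std) %||% paste0("y", seq_len(nrow(beta)))
  dimnames(beta) <- list(mrna_ids, mirna_ids)
  names(intercepts) <- mrna_ids
  structure(list(beta = beta, intercepts = intercepts,
                 mirna_ids = mirna_ids, mrna_ids = mrna_ids),
            class = "AssociationMatrix")
}

#' Predict responses from original-scale association scores
#'
#' @param assoc An `AssociationMatrix`.
#' @param X_new Samples x miRNAs matrix on the original (log2) scale, columns
#'   in `assoc$mirna_ids` order.
#' @return Samples x mRNAs matrix of predictions.
#' @export
predict_associations <- function(assoc, X_new) {
  stopifnot(inherits(assoc, "AssociationMatrix"))
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1L)
  if (ncol(X_new) != length(assoc$mirna_ids)) {
    stopf("X_new has %d columns, expected %d", ncol(X_new),
          length(assoc$mirna_ids))
  }
  out <- X_new %*% t(assoc$beta)
  sweep(out, 2L, assoc$intercepts, "+")
}

# Stacked per-response PLS1 association scores: one single-response PLS fit
# of each mRNA on the full miRNA design, back-transformed to the original
# scale. This is the pipeline's observed statistic: it is the same
# functional of the data that each bootstrap replicate recomputes, which the
# significance test requires.
association_scores_pls1 <- function(X, Y, ncomp = 3L) {
  Xs <- standardize(X)
  m <- ncol(Y); p <- ncol(X)
  beta <- matrix(0, m, p)
  for (i in seq_len(m)) {
    y <- Y[, i]
    my <- mean(y); sdy <- stats::sd(y)
    if (sdy == 0) stopf("zero-variance mRNA column %d", i)
    beta[i, ] <- pls1_coef_std(Xs$values, (y - my) / sdy, ncomp) * sdy / Xs$sds
  }
  mirna_ids <- colnames(X) %||% paste0("x", seq_len(p))
  mrna_ids <- colnames(Y) %||% paste0("y", seq_len(m))
  dimnames(beta) <- list(mrna_ids, mirna_ids)
  intercepts <- colMeans(Y) - as.vector(beta %*% colMeans(X))
  names(intercepts) <- mrna_ids
  structure(list(beta = beta, intercepts = intercepts,
                 mirna_ids = mirna_ids, mrna_ids = mrna_ids),
            class = "AssociationMatrix")
}

#' PLS association scores for a paired dataset
#'
#' Computes the original-scale association score matrix `beta[i, j]` linking
#' every selected mRNA `i` to every selected miRNA `j`: each mRNA is fitted
#' by a single-response PLS regression on the full miRNA design ("for each
#' mRNA" — the per-response formulation the significance test bootstraps),
#' and the standardized coefficients are back-transformed.
#'
#' @param data A `PairedDataset` (log2 blocks).
#' @param mirna_ids,mrna_ids Gene subsets to use (defaults: all).
#' @param ncomp Number of latent components per fit (default 3).
#' @return An `AssociationMatrix`.
#' @export
pls_association_scores <- function(data, mirna_ids = NULL, mrna_ids = NULL,
                                   ncomp = 3L) {
  stopifnot(inherits(data, "PairedDataset"))
  X <- t(data$mirna$values[mirna_ids %||% rownames(data$mirna$values), ,
                           drop = FALSE])
  Y <- t(data$mrna$values[mrna_ids %||% rownames(data$mrna$values), ,
                          drop = FALSE])
  association_scores_pls1(X, Y, ncomp = ncomp)
}
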