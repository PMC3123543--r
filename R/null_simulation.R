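#' Sample a uniform derangement
#'
#' Draws a permutation of `1..n` with no fixed point, uniformly among all
#' derangements, by rejection sampling from uniform permutations.
#'
#' @param n Permutation size, at least 2.
#' @param rng_seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Integer vector: a permutation with `perm[s] != s` for all `s`.
#' @export
sample_derangement <- function(n, rng_seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stopf("no derangement exists for n < 2")
  draw <- function() {
    repeat {
      perm <- sample.int(n)
      if (!any(perm == seq_len(n))) return(perm)
    }
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

#' Break the sample pairing of a paired dataset
#'
#' Reorders the mRNA block's columns by a random derangement while the miRNA
#' block stays fixed, so no sample's mRNA array remains aligned with its own
#' miRNA array. Per-gene marginal distributions are unchanged; any
#' association between the blocks is destroyed, so pairs called significant
#' on the result are chance calls.
#'
#' @param data A `PairedDataset` with `n >= 2`.
#' @param rng_seed Optional seed (see [sample_derangement()]).
#' @return A `PairedDataset`; the applied derangement is attached as
#'   attribute `"derangement"`.
#' @export
permute_dataset <- function(data, rng_seed = NULL) {
  stopifnot(inherits(data, "PairedDataset"))
  perm <- sample_derangement(data$n, rng_seed)
  vals <- data$mrna$values[, perm, drop = FALSE]
  colnames(vals) <- colnames(data$mrna$values)  # labels keep the (now false) pairing
  out <- data
  out$mrna <- expression_matrix(vals, is_log2 = data$mrna$is_log2)
  attr(out, "derangement") <- perm
  out
}

#' Pairwise-correlation pair calling
#'
#' The simple baseline: a (miRNA, mRNA) pair is called significant when its
#' sample correlation falls at or below `r_threshold`.
#'
#' @param data A `PairedDataset` with `n >= 3`.
#' @param r_threshold Correlation cutoff (e.g. -0.75).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return A `SignificantPairSet` data frame with columns `mirna_id`,
#'   `mrna_id`, `r`.
#' @export
correlation_significant_pairs <- function(data, r_threshold,
                                          cor_method = c("pearson", "spearman")) {
  stopifnot(inherits(data, "PairedDataset"))
  cor_method <- match.arg(cor_method)
  if (data$n < 3L) stopf("need at least 3 samples for correlations")
  R <- pair_correlations(data, cor_method)
  hit <- which(R <= r_threshold, arr.ind = TRUE)
  out <- data.frame(
    mirna_id = colnames(R)[hit[, 2L]],
    mrna_id = rownames(R)[hit[, 1L]],
    r = R[hit],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("SignificantPairSet", "data.frame"),
            r_threshold = r_threshold, cor_method = cor_method)
}

# m x p matrix of mRNA-by-miRNA sample correlations
pair_correlations <- function(data, cor_method = "pearson") {
  X <- t(data$mirna$values)  # n x p
  Y <- t(data$mrna$values)   # n x m
  sx <- apply(X, 2L, stats::sd); sy <- apply(Y, 2L, stats::sd)
  if (any(sx == 0)) stopf("zero-variance miRNA: '%s'", colnames(X)[sx == 0][1L])
  if (any(sy == 0)) stopf("zero-variance mRNA: '%s'", colnames(Y)[sy == 0][1L])
  stats::cor(Y, X, method = cor_method)
}

default_grid <- function(method) {
  if (method == "pls") seq(0.01, 0.50, by = 0.01)
  else seq(-1, -0.5, by = 0.005)
}

#' Estimate the chance false detection rate of a pair-calling rule
#'
#' Repeatedly destroys the miRNA/mRNA sample pairing with a random
#' derangement ([permute_dataset()]), applies the pair-calling rule to each
#' association-free dataset, and reports the fraction of all tested pairs
#' called significant:
#' `rate = total false positives / (n_simulations * m * p)`.
#' A threshold sweep over `threshold_grid` is computed from the same
#' simulated datasets.
#'
#' Note this "false detection rate" is a simulation-based chance-call
#' estimate, distinct from the Benjamini-Hochberg false discovery rate used
#' inside the PLS caller.
#'
#' @param data A `PairedDataset` (log2 blocks).
#' @param method `"correlation"` (threshold on r) or `"pls"` (threshold on
#'   the bootstrap q-value).
#' @param threshold Headline threshold to report (default 0.3 for `"pls"`,
#'   -0.75 for `"correlation"`).
#' @param n_simulations Number of deranged datasets (paper-scale default
#'   1000; scale down for desk use).
#' @param rng_seed Master seed; simulation `s` uses a derived substream.
#' @param threshold_grid Sweep grid; defaults to q in 0.01..0.50 (step 0.01)
#'   or r in -1..-0.5 (step 0.005).
#' @param ncomp,B Passed to [run_target_prediction()] when `method = "pls"`.
#' @param cor_method Passed to the correlation caller.
#' @return A `FalseDetectionEstimate`: list with `threshold`,
#'   `n_simulations`, `total_pairs`, `false_positives`, `rate`,
#'   `rate_percent` and `sweep` (data frame: threshold, false_positives,
#'   total_pairs, rate_percent).
#' @export
estimate_false_detection_rate <- function(data,
                                          method = c("correlation", "pls"),
                                          threshold = NULL,
                                          n_simulations = 1000L,
                                          rng_seed = 1L,
                                          threshold_grid = NULL,
                                          ncomp = 3L, B = 1000L,
                                          cor_method = "pearson") {
  stopifnot(inherits(data, "PairedDataset"))
  method <- match.arg(method)
  n_simulations <- as.integer(n_simulations)
  if (n_simulations < 1L) stopf("'n_simulations' must be at least 1")
  threshold <- threshold %||% if (method == "pls") 0.3 else -0.75
  grid <- sort(unique(c(threshold_grid %||% default_grid(method), threshold)))
  m <- nrow(data$mrna$values); p <- nrow(data$mirna$values)
  counts <- numeric(length(grid))
  for (s in seq_len(n_simulations)) {
    perm_data <- permute_dataset(data, rng_seed = pair_seed(rng_seed, s, 0L))
    stat <- if (method == "correlation") {
      pair_correlations(perm_data, cor_method)
    } else {
      res <- run_target_prediction(
        perm_data,
        down_mirnas = rownames(data$mirna$values),
        up_mrnas = rownames(data$mrna$values),
        ncomp = ncomp, B = B, fdr_threshold = threshold,
        rng_seed = pair_seed(rng_seed, s, 1L))
      # chance calls require the negative direction, as in the real pipeline
      ifelse(res$tests$beta_observed < 0, res$tests$q_value, Inf)
    }
    sorted <- sort(as.vector(stat))
    counts <- counts + findInterval(grid, sorted)
  }
  total <- as.double(n_simulations) * m * p
  sweep_tab <- data.frame(threshold = grid,
                          false_positives = counts,
                          total_pairs = total,
                          rate_percent = 100 * counts / total)
  k <- match(threshold, grid)
  structure(list(
    method = method, threshold = threshold,
    n_simulations = n_simulations, total_pairs = total,
    false_positives = counts[k], rate = counts[k] / total,
    rate_percent = 100 * counts[k] / total, sweep = sweep_tab
  ), class = "FalseDetectionEstimate")
}

#' @export
print.FalseDetectionEstimate <- function(x, ...) {
  cat(sprintf("False detection rate (%s caller, threshold %g): %.3f%% (%d/%g pairs over %d simulations)\n",
              x$method, x$threshold, x$rate_percent, x$false_positives,
              x$total_pairs, x$n_simulations))
  invisible(x)
}

#' Calibrate the correlation threshold to a target false detection rate
#'
#' Sweeps the correlation threshold grid on deranged data and returns the
#' grid point whose estimated false detection rate is closest to
#' `target_rate` without exceeding it (the conservative reading of "the
#' same rate as").
#'
#' @param data A `PairedDataset`.
#' @param target_rate Target rate as a proportion in (0, 1), e.g. 0.025.
#' @param n_simulations,rng_seed,threshold_grid,cor_method As in
#'   [estimate_false_detection_rate()].
#' @return The selected threshold (scalar), with the sweep table attached as
#'   attribute `"sweep"`.
#' @export
calibrate_correlation_threshold <- function(data, target_rate,
                                            n_simulations = 1000L,
                                            rng_seed = 1L,
                                            threshold_grid = NULL,
                                            cor_method = "pearson") {
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= 1) {
    stopf("'target_rate' must lie in (0, 1)")
  }
  grid <- threshold_grid %||% default_grid("correlation")
  est <- estimate_false_detection_rate(
    data, method = "correlation", threshold = grid[1L],
    n_simulations = n_simulations, rng_seed = rng_seed,
    threshold_grid = grid, cor_method = cor_method)
  sweep_tab <- est$sweep
  ok <- sweep_tab$rate_percent <= 100 * target_rate
  if (!any(ok)) {
    stopf("no grid threshold attains a rate <= %.4g%%; extend the grid",
          100 * target_rate)
  }
  sel <- max(which(ok))  # largest (least strict) threshold not exceeding target
  structure(sweep_tab$threshold[sel], sweep = sweep_tab)
}
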