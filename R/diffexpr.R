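#' Unpaired two-sample t-test
#'
#' Computed from the textbook formulas so the variance model is explicit.
#' `variance_mode = "welch"` uses the Welch-Satterthwaite statistic and
#' degrees of freedom; `"pooled"` the equal-variance statistic with
#' `n1 + n2 - 2` degrees of freedom. The p-value is two-sided. If both
#' groups have zero variance and equal means the test is degenerate and
#' returns `t = 0, p = 1` by convention; zero variance with unequal means
#' returns an infinite statistic and `p = 0`.
#'
#' @param values_group1,values_group2 Numeric vectors, at least 2 finite
#'   values each.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @return Named list with `t_statistic` (sign of `mean1 - mean2`),
#'   `p_value` and `df`.
#' @export
unpaired_t_test <- function(values_group1, values_group2,
                            variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  x <- as.numeric(values_group1)
  y <- as.numeric(values_group2)
  if (length(x) < 2L || length(y) < 2L) {
    stopf("each group needs at least 2 values")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("values must be finite")
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (variance_mode == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0) se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else NA_real_
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (d == 0) return(list(t_statistic = 0, p_value = 1, df = df))
    return(list(t_statistic = sign(d) * Inf, p_value = 0, df = df))
  }
  t_stat <- d / sqrt(se2)
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(t_statistic = t_stat, p_value = p, df = df)
}

#' Benjamini-Hochberg step-up q-values
#'
#' The step-up adjustment: with sorted p-values `p_(1) <= ... <= p_(M)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * M / j)`, mapped back to input order.
#' Rejecting all tests with `q <= alpha` reproduces the BH rejection set at
#' level `alpha`. Ties are handled by a stable sort on input index.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1] with no missing entries")
  }
  m <- length(p)
  ord <- order(p)  # stable in R: ties keep input order
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Differential expression screen
#'
#' Per-gene unpaired t-test of tumor vs normal on a log2 expression block,
#' BH q-values across all genes of the block, and a signed fold change from
#' anti-logged group means: `r = 2^(mean_tumor - mean_normal)`, reported as
#' `r` if `r >= 1`, otherwise `-1/r`. A gene is called `up` (`down`) when
#' the tumor mean is higher (lower), `q <= q_cutoff` and
#' `|signed_fold_change| >= fc_cutoff`; otherwise its direction is `none`.
#'
#' @param block A log2 `ExpressionMatrix`.
#' @param annotation A [sample_annotation()] with both groups present among
#'   the block's samples.
#' @param q_cutoff BH q-value cutoff (default 0.10).
#' @param fc_cutoff Absolute linear fold-change cutoff (default 1.2).
#' @param variance_mode Passed to [unpaired_t_test()].
#' @return Data frame with one row per gene: `gene_id`,
#'   `mean_log2_tumor`, `mean_log2_normal`, `signed_fold_change`,
#'   `t_statistic`, `p_value`, `q_value`, `direction`.
#' @export
select_differential <- function(block, annotation, q_cutoff = 0.10,
                                fc_cutoff = 1.2,
                                variance_mode = c("welch", "pooled")) {
  stopifnot(inherits(block, "ExpressionMatrix"),
            inherits(annotation, "SampleAnnotation"))
  variance_mode <- match.arg(variance_mode)
  if (!block$is_log2) stopf("block must be log2-transformed (run floor_and_log2 first)")
  ann <- annotation[annotation$sample_id %in% colnames(block$values), ,
                    drop = FALSE]
  tumor <- ann$sample_id[ann$group == "tumor"]
  normal <- ann$sample_id[ann$group == "normal"]
  if (length(tumor) < 2L || length(normal) < 2L) {
    stopf("need at least 2 samples per group")
  }
  vt <- block$values[, tumor, drop = FALSE]
  vn <- block$values[, normal, drop = FALSE]
  tests <- lapply(seq_len(nrow(vt)), function(i) {
    unpaired_t_test(vt[i, ], vn[i, ], variance_mode)
  })
  mt <- rowMeans(vt)
  mn <- rowMeans(vn)
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  q <- benjamini_hochberg(p)
  ratio <- 2^(mt - mn)
  sfc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  pass <- q <= q_cutoff & abs(sfc) >= fc_cutoff
  direction <- ifelse(!pass, "none", ifelse(mt > mn, "up", "down"))
  data.frame(
    gene_id = rownames(block$values),
    mean_log2_tumor = mt,
    mean_log2_normal = mn,
    signed_fold_change = sfc,
    t_statistic = vapply(tests, `[[`, numeric(1), "t_statistic"),
    p_value = p,
    q_value = q,
    direction = direction,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
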