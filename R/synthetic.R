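#' Ground truth for a synthetic paired dataset
#'
#' Describes the generative world of [generate_paired_dataset()]: planted
#' inverse regulatory edges (negative original-scale coefficients), Gaussian
#' noise, block-correlated miRNA covariates, and tumor-vs-normal group
#' shifts for the differential-expression stage.
#'
#' @param p_mirna,m_mrna Numbers of miRNAs and mRNAs.
#' @param n_edges Number of planted (mRNA, miRNA) edges; ignored when
#'   `true_beta` is supplied.
#' @param edge_beta Coefficient of each planted edge on the log2 scale
#'   (must be negative; default -1: one log2 unit up in the miRNA drives
#'   one unit down in the target).
#' @param true_beta Optional explicit m x p coefficient matrix (entries
#'   must be <= 0; nonzero entries are the planted edges).
#' @param noise_sd Residual sd of the mRNA model on the log2 scale
#'   (default 0.25).
#' @param rho Within-block correlation of the miRNA covariates in `[0, 1)`
#'   (default 0.6).
#' @param block_size miRNAs per collinearity block (default 5).
#' @param mirna_shift,mrna_shift Tumor-minus-normal log2 group shifts
#'   (defaults -1 and +1: miRNAs down, mRNAs up in tumor, fold change 2).
#' @param seed Integer seed; data are a pure function of (truth, seed).
#' @return A `SyntheticGroundTruth` list.
#' @export
synthetic_ground_truth <- function(p_mirna, m_mrna, n_edges = 4L,
                                   edge_beta = -1, true_beta = NULL,
                                   noise_sd = 0.25, rho = 0.6,
                                   block_size = 5L,
                                   mirna_shift = -1, mrna_shift = 1,
                                   seed = 1L) {
  p <- as.integer(p_mirna); m <- as.integer(m_mrna)
  if (p < 1L || m < 1L) stopf("dimensions must be positive")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) stopf("'rho' must lie in [0, 1)")
  if (noise_sd <= 0) stopf("'noise_sd' must be positive")
  if (is.null(true_beta)) {
    if (any(edge_beta >= 0)) stopf("planted edges must have negative coefficients")
    n_edges <- as.integer(n_edges)
    if (n_edges > p * m) stopf("more edges than pairs")
    true_beta <- matrix(0, m, p)
    if (n_edges > 0L) {
      cells <- with_seed(seed, sample.int(p * m, n_edges))
      true_beta[cells] <- rep_len(edge_beta, n_edges)
    }
  } else {
    true_beta <- as.matrix(true_beta)
    if (nrow(true_beta) != m || ncol(true_beta) != p) {
      stopf("'true_beta' must be %d x %d", m, p)
    }
    if (any(true_beta > 0)) stopf("planted edges must have negative coefficients")
  }
  dimnames(true_beta) <- list(default_mrna_ids(m), default_mirna_ids(p))
  structure(list(
    p_mirna = p, m_mrna = m, true_beta = true_beta, noise_sd = noise_sd,
    rho = rho, block_size = as.integer(block_size),
    mirna_shift = mirna_shift, mrna_shift = mrna_shift, seed = as.integer(seed)
  ), class = "SyntheticGroundTruth")
}

default_mirna_ids <- function(p) sprintf("miR-%03d", seq_len(p))
default_mrna_ids <- function(m) sprintf("GENE%03d", seq_len(m))

#' Generate a synthetic paired miRNA/mRNA dataset with known truth
#'
#' Emulates the shape of a paired tumor/normal microarray study: a
#' block-correlated Gaussian miRNA block (down-shifted in tumor), and an
#' mRNA block generated from the linear model
#' `Y_i = beta0_i + sum_j true_beta[i, j] * X_j + N(0, noise_sd)` plus its
#' own tumor up-shift. Both blocks are returned as raw intensities
#' (`2^log2`), so [floor_and_log2()] round-trips the full pipeline. Log2
#' baselines sit near 10, far above the background floor of 32 (log2 = 5),
#' so flooring is a no-op on clean synthetic data.
#'
#' @param n_tumor,n_normal Group sizes (defaults 7 and 4, the paired-study
#'   shape this generator emulates).
#' @param truth A [synthetic_ground_truth()]; built from `...` if omitted.
#' @param ... Passed to [synthetic_ground_truth()] when `truth` is missing
#'   (requires at least `p_mirna` and `m_mrna`).
#' @return List with `mirna_raw` and `mrna_raw` (raw-scale
#'   `ExpressionMatrix` objects), `annotation`, `truth`, and `paired` (the
#'   processed log2 `PairedDataset` ready for the pipeline).
#' @export
generate_paired_dataset <- function(n_tumor = 7L, n_normal = 4L,
                                    truth = NULL, ...) {
  if (is.null(truth)) truth <- synthetic_ground_truth(...)
  stopifnot(inherits(truth, "SyntheticGroundTruth"))
  n <- n_tumor + n_normal
  if (n < 4L) stopf("need at least 4 samples")
  p <- truth$p_mirna; m <- truth$m_mrna
  sample_ids <- c(sprintf("T%02d", seq_len(n_tumor)),
                  sprintf("N%02d", seq_len(n_normal)))
  tumor <- c(rep(1, n_tumor), rep(0, n_normal))
  blocks <- ceiling(seq_len(p) / truth$block_size)
  mirna_base <- 10; mrna_base <- 10

  out <- with_seed(truth$seed + 1L, {
    Z <- matrix(stats::rnorm(max(blocks) * n), max(blocks), n)  # shared block factors
    E <- matrix(stats::rnorm(p * n), p, n)
    X <- sqrt(truth$rho) * Z[blocks, , drop = FALSE] +
      sqrt(1 - truth$rho) * E
    X <- mirna_base + X + truth$mirna_shift * matrix(tumor, p, n, byrow = TRUE)
    beta0 <- mrna_base - as.vector(truth$true_beta %*% rep(mirna_base, p))
    Y <- matrix(beta0, m, n) + truth$true_beta %*% X +
      truth$mrna_shift * matrix(tumor, m, n, byrow = TRUE) +
      matrix(stats::rnorm(m * n, sd = truth$noise_sd), m, n)
    list(X = X, Y = Y)
  })
  mirna_raw <- expression_matrix(2^out$X,
                                 gene_ids = colnames(truth$true_beta),
                                 sample_ids = sample_ids)
  mrna_raw <- expression_matrix(2^out$Y,
                                gene_ids = rownames(truth$true_beta),
                                sample_ids = sample_ids)
  ann <- sample_annotation(sample_ids,
                           ifelse(tumor == 1, "tumor", "normal"))
  paired <- pair_blocks(floor_and_log2(mirna_raw), floor_and_log2(mrna_raw),
                        ann)
  list(mirna_raw = mirna_raw, mrna_raw = mrna_raw, annotation = ann,
       truth = truth, paired = paired)
}

#' Score recovery of planted edges
#'
#' @param called A `SignificantPairSet` (or data frame with `mirna_id`,
#'   `mrna_id`).
#' @param truth The generating [synthetic_ground_truth()].
#' @return A `RecoveryReport` list: `tp`, `fp`, `fn`, `precision`,
#'   `recall`. With no calls, precision is 1 by convention.
#' @export
score_recovery <- function(called, truth) {
  stopifnot(inherits(truth, "SyntheticGroundTruth"))
  planted <- which(truth$true_beta < 0, arr.ind = TRUE)
  planted_key <- paste(colnames(truth$true_beta)[planted[, 2L]],
                       rownames(truth$true_beta)[planted[, 1L]], sep = "\r")
  called_key <- if (nrow(called)) {
    paste(called$mirna_id, called$mrna_id, sep = "\r")
  } else character(0)
  unknown <- c(setdiff(called$mirna_id, colnames(truth$true_beta)),
               setdiff(called$mrna_id, rownames(truth$true_beta)))
  if (length(unknown)) stopf("called pair references unknown ID '%s'", unknown[1L])
  tp <- length(intersect(called_key, planted_key))
  fp <- length(setdiff(called_key, planted_key))
  fn <- length(setdiff(planted_key, called_key))
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0L) 1 else tp / (tp + fn)
  ), class = "RecoveryReport")
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat(sprintf("RecoveryReport: TP %d, FP %d, FN %d; precision %.3f, recall %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

#' Write a synthetic dataset to pipeline-ready TSV files
#'
#' Emits the same tab-delimited dialect [read_expression_table()] reads
#' (raw intensities), the annotation TSV, and the planted-truth edge list.
#'
#' @param synth Output of [generate_paired_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirna = file.path(dir, "mirna_raw.tsv"),
             mrna = file.path(dir, "mrna_raw.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth_edges.tsv"))
  write_expression_table(synth$mirna_raw, paths[["mirna"]])
  write_expression_table(synth$mrna_raw, paths[["mrna"]])
  utils::write.table(synth$annotation, paths[["annotation"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  planted <- which(synth$truth$true_beta < 0, arr.ind = TRUE)
  truth_df <- data.frame(
    mirna_id = colnames(synth$truth$true_beta)[planted[, 2L]],
    mrna_id = rownames(synth$truth$true_beta)[planted[, 1L]],
    true_beta = synth$truth$true_beta[planted],
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_df, paths[["truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
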