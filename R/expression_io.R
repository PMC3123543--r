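#' Expression matrix container
#'
#' A minimal genes x samples container used throughout the pipeline. Values
#' are raw fluorescence intensities on input and log2 intensities after
#' [floor_and_log2()].
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: rownames of `values`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: colnames of `values`).
#' @param is_log2 Logical; `TRUE` once values are floored and log2-scaled.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (dimnamed numeric matrix) and `is_log2`.
#' @examples
#' m <- expression_matrix(matrix(2^(5:10), 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' floor_and_log2(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              is_log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stopf("identifier lengths do not match matrix dimensions")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("duplicate gene ID: '%s'", dup[1L])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicate sample ID: '%s'", dup[1L])
  if (anyNA(values)) stopf("missing values are not supported")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, is_log2 = isTRUE(is_log2)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log2) "log2" else "raw"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a tab-delimited expression table
#'
#' Expected layout: header row `gene_id<TAB>sample1<TAB>...`, one gene per
#' row, numeric body. Duplicated gene IDs, ragged rows and non-numeric cells
#' are hard errors with coordinates; nothing is imputed.
#'
#' @param path Path to a tab-delimited text file.
#' @return An [expression_matrix()] with `is_log2 = FALSE`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "",
                                comment.char = "")
  if (length(fields) < 2L) stopf("'%s': need a header row and at least one gene row", path)
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1L])[1L]
    stopf("'%s': ragged row %d (%d fields, expected %d)",
          path, bad, fields[bad], fields[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "")
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("'%s': duplicate gene ID: '%s'", path, dup[1L])
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("'%s': non-numeric value '%s' at row %d, column %d",
          path, body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L])
  }
  expression_matrix(num, gene_ids = gene_ids, sample_ids = colnames(df)[-1L],
                    is_log2 = FALSE)
}

#' Write an expression matrix as a tab-delimited table
#'
#' Uses full precision (`%.17g`) so that write -> read round-trips
#' bit-identically.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(x$values))
  lines <- paste(rownames(x$values),
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Background-floor and log2-transform raw intensities
#'
#' Intensities below the background floor (default 32) carry no signal and
#' are clamped to it before log2 transformation, so every transformed entry
#' is at least `log2(floor)` (5 at the default).
#'
#' @param raw An `ExpressionMatrix` with `is_log2 = FALSE`.
#' @param floor Positive background threshold; default 32.
#' @return The transformed `ExpressionMatrix` (`is_log2 = TRUE`).
#' @export
floor_and_log2 <- function(raw, floor = 32) {
  stopifnot(inherits(raw, "ExpressionMatrix"))
  if (raw$is_log2) stopf("input is already log2-transformed")
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0) {
    stopf("'floor' must be a single positive number")
  }
  if (any(!is.finite(raw$values))) stopf("raw values must be finite")
  vals <- log2(pmax(raw$values, floor))
  expression_matrix(vals, is_log2 = TRUE)
}

#' Sample annotation (tumor/normal labels)
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param group Character vector, one of `"tumor"`/`"normal"` per sample.
#' @return A `SampleAnnotation` data frame with columns `sample_id`, `group`.
#' @export
sample_annotation <- function(sample_ids, group) {
  sample_ids <- as.character(sample_ids)
  group <- as.character(group)
  if (length(sample_ids) != length(group)) {
    stopf("'sample_ids' and 'group' lengths differ")
  }
  if (anyDuplicated(sample_ids)) stopf("duplicate sample IDs in annotation")
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad)) stopf("unknown group label '%s'", bad[1L])
  structure(data.frame(sample_id = sample_ids, group = group,
                       stringsAsFactors = FALSE),
            class = c("SampleAnnotation", "data.frame"))
}

#' Read a two-column sample annotation table
#'
#' @param path Path to a TSV with header `sample_id<TAB>group`.
#' @return A [sample_annotation()].
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stopf("'%s': expected columns sample_id, group", path)
  sample_annotation(df[[1L]], df[[2L]])
}

#' Pair the miRNA and mRNA blocks on their common samples
#'
#' Both blocks are restricted to their common sample IDs and reordered to the
#' canonical order (the miRNA block's order restricted to the intersection),
#' so downstream results do not depend on input column order. Samples absent
#' from one block are dropped with a message.
#'
#' @param mirna,mrna `ExpressionMatrix` objects measured on overlapping
#'   sample sets.
#' @param annotation A [sample_annotation()] covering every retained sample.
#' @return A `PairedDataset`: list with `mirna`, `mrna`, `annotation`, `n`.
#' @export
pair_blocks <- function(mirna, mrna, annotation) {
  stopifnot(inherits(mirna, "ExpressionMatrix"),
            inherits(mrna, "ExpressionMatrix"),
            inherits(annotation, "SampleAnnotation"))
  common <- intersect(colnames(mirna$values), colnames(mrna$values))
  if (length(common) == 0L) stopf("the miRNA and mRNA blocks share no samples")
  # canonical order: miRNA block order restricted to the intersection
  common <- colnames(mirna$values)[colnames(mirna$values) %in% common]
  missing_ann <- setdiff(common, annotation$sample_id)
  if (length(missing_ann)) {
    stopf("sample '%s' present in the expression blocks but absent from the annotation",
          missing_ann[1L])
  }
  dropped <- setdiff(union(colnames(mirna$values), colnames(mrna$values)),
                     common)
  if (length(dropped)) {
    message(sprintf("pair_blocks: dropped %d unmatched sample(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  ann <- annotation[match(common, annotation$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("SampleAnnotation", "data.frame")
  out <- list(
    mirna = expression_matrix(mirna$values[, common, drop = FALSE],
                              is_log2 = mirna$is_log2),
    mrna = expression_matrix(mrna$values[, common, drop = FALSE],
                             is_log2 = mrna$is_log2),
    annotation = ann,
    n = length(common)
  )
  structure(out, class = "PairedDataset")
}

#' @export
print.PairedDataset <- function(x, ...) {
  cat(sprintf("PairedDataset: %d samples (%d tumor, %d normal); %d miRNAs, %d mRNAs\n",
              x$n, sum(x$annotation$group == "tumor"),
              sum(x$annotation$group == "normal"),
              nrow(x$mirna$values), nrow(x$mrna$values)))
  invisible(x)
}
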