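#' Build the bipartite miRNA:mRNA association network
#'
#' Nodes are the distinct miRNAs and mRNAs that appear in at least one
#' significant pair (candidates with no significant edge are not nodes);
#' edges connect miRNA to mRNA only.
#'
#' @param pairs A `SignificantPairSet` or data frame with columns
#'   `mirna_id`, `mrna_id` and optionally `beta` (or `r`) and `q_value`.
#' @return An `AssociationNetwork`: list with `nodes` (data frame `id`,
#'   `kind`), `edges` (data frame `mirna_id`, `mrna_id`, `beta`,
#'   `q_value`), `n_nodes`, `n_edges`, and `mrna_degree` (per-mRNA
#'   in-degree, supporting multi-targeting summaries such as how many
#'   members of a miRNA family hit one mRNA).
#' @export
build_bipartite_network <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs)) {
    key <- paste(pairs$mirna_id, pairs$mrna_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- pairs[duplicated(key), ][1L, ]
      stopf("duplicate pair: (%s, %s)", d$mirna_id, d$mrna_id)
    }
  }
  beta <- pairs$beta %||% pairs$r %||% rep(NA_real_, nrow(pairs))
  qv <- pairs$q_value %||% rep(NA_real_, nrow(pairs))
  edges <- data.frame(mirna_id = as.character(pairs$mirna_id %||% character(0)),
                      mrna_id = as.character(pairs$mrna_id %||% character(0)),
                      beta = as.numeric(beta), q_value = as.numeric(qv),
                      stringsAsFactors = FALSE)
  mirnas <- sort(unique(edges$mirna_id))
  mrnas <- sort(unique(edges$mrna_id))
  nodes <- data.frame(id = c(mirnas, mrnas),
                      kind = rep(c("miRNA", "mRNA"),
                                 c(length(mirnas), length(mrnas))),
                      stringsAsFactors = FALSE)
  deg <- table(factor(edges$mrna_id, levels = mrnas))
  structure(list(
    nodes = nodes, edges = edges,
    n_nodes = nrow(nodes), n_edges = nrow(edges),
    mrna_degree = data.frame(mrna_id = mrnas,
                             degree = as.integer(deg),
                             stringsAsFactors = FALSE)
  ), class = "AssociationNetwork")
}

#' @export
print.AssociationNetwork <- function(x, ...) {
  cat(sprintf("AssociationNetwork: %d nodes (%d miRNA, %d mRNA), %d edges\n",
              x$n_nodes, sum(x$nodes$kind == "miRNA"),
              sum(x$nodes$kind == "mRNA"), x$n_edges))
  invisible(x)
}

fmt12 <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

#' Export an association network
#'
#' Formats: `"sif"` (Cytoscape simple interaction:
#' `mirna<TAB>targets<TAB>mrna`), `"graphml"` (node `kind` and edge
#' `beta`/`q_value` attributes; numbers serialized with 12 significant
#' digits), `"tsv"` (edge list with attributes).
#'
#' @param net An `AssociationNetwork`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "AssociationNetwork"))
  format <- match.arg(format)
  e <- net$edges
  lines <- switch(format,
    sif = if (nrow(e)) paste(e$mirna_id, "targets", e$mrna_id, sep = "\t")
          else character(0),
    tsv = c("mirna_id\tmrna_id\tbeta\tq_value",
            if (nrow(e)) paste(e$mirna_id, e$mrna_id, fmt12(e$beta),
                               fmt12(e$q_value), sep = "\t")),
    graphml = graphml_lines(net)
  )
  writeLines(lines, path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

graphml_lines <- function(net) {
  n <- net$nodes; e <- net$edges
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '  <key id="beta" for="edge" attr.name="beta" attr.type="double"/>',
    '  <key id="q_value" for="edge" attr.name="q_value" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    if (nrow(n)) sprintf('    <node id="%s"><data key="kind">%s</data></node>',
                         xml_escape(n$id), n$kind),
    if (nrow(e)) sprintf(paste0('    <edge source="%s" target="%s">',
                                '<data key="beta">%s</data>',
                                '<data key="q_value">%s</data></edge>'),
                         xml_escape(e$mirna_id), xml_escape(e$mrna_id),
                         fmt12(e$beta), fmt12(e$q_value)),
    '  </graph>',
    '</graphml>')
}

#' Import an association network written by [export_network()]
#'
#' @param path File path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return An `AssociationNetwork`. SIF carries no attributes, so `beta`
#'   and `q_value` come back as `NA` for that format.
#' @export
import_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    ln <- readLines(path)
    ln <- ln[nzchar(ln)]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 3L)
    if (length(bad)) stopf("'%s': malformed SIF line %d", path, bad[1L])
    df <- data.frame(mirna_id = vapply(parts, `[[`, character(1), 1L),
                     mrna_id = vapply(parts, `[[`, character(1), 3L),
                     stringsAsFactors = FALSE)
    return(build_bipartite_network(df))
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    return(build_bipartite_network(df))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  edges <- xml2::xml_find_all(doc, ".//edge")
  df <- data.frame(
    mirna_id = xml2::xml_attr(edges, "source"),
    mrna_id = xml2::xml_attr(edges, "target"),
    beta = as.numeric(xml2::xml_text(
      xml2::xml_find_first(edges, "./data[@key='beta']"))),
    q_value = as.numeric(xml2::xml_text(
      xml2::xml_find_first(edges, "./data[@key='q_value']"))),
    stringsAsFactors = FALSE
  )
  build_bipartite_network(df)
}

#' Overlap between predicted target sets and external prediction lists
#'
#' Compares the package's per-miRNA target sets with externally generated
#' lists (e.g. sequence-based predictors). Gene symbols are upper-cased and
#' whitespace-trimmed before comparison. Two summary conventions are
#' reported: the unweighted mean of per-miRNA percentages, and the pooled
#' percentage `100 * sum(overlaps) / sum(predicted set sizes)`.
#'
#' @param targets_by_mirna Named list: miRNA ID -> character vector of
#'   predicted target gene symbols.
#' @param external_by_mirna Named list: miRNA ID -> character vector from
#'   the external predictor.
#' @return List with `per_mirna` (data frame: `mirna_id`, `n_targets`,
#'   `n_external`, `n_overlap`, `pct_overlap`), `average_unweighted`, and
#'   `average_pooled`.
#' @export
prediction_overlap <- function(targets_by_mirna, external_by_mirna) {
  norm <- function(x) unique(toupper(trimws(as.character(x))))
  ids <- names(targets_by_mirna)
  if (is.null(ids)) stopf("'targets_by_mirna' must be a named list")
  rows <- lapply(ids, function(id) {
    mine <- norm(targets_by_mirna[[id]])
    ext <- if (id %in% names(external_by_mirna)) {
      norm(external_by_mirna[[id]])
    } else character(0)
    ov <- length(intersect(mine, ext))
    data.frame(mirna_id = id,
               n_targets = length(mine),
               n_external = length(ext),
               n_overlap = ov,
               pct_overlap = if (length(mine)) 100 * ov / length(mine) else 0,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_mirna = per,
       average_unweighted = mean(per$pct_overlap),
       average_pooled = if (sum(per$n_targets) > 0) {
         100 * sum(per$n_overlap) / sum(per$n_targets)
       } else 0)
}

#' Read external per-miRNA target lists
#'
#' Accepts the two-column TSV dialect `mirna_id<TAB>gene_symbol` (one pair
#' per line, no header required; a header line starting with `mirna_id` is
#' skipped).
#'
#' @param path File path.
#' @return Named list: miRNA ID -> character vector of gene symbols.
#' @export
read_target_lists <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) && grepl("^mirna_id\t", ln[1L])) ln <- ln[-1L]
  if (!length(ln)) return(list())
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stopf("'%s': malformed line %d (need mirna<TAB>gene)", path, bad[1L])
  df <- data.frame(mirna = vapply(parts, `[[`, character(1), 1L),
                   gene = vapply(parts, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  lapply(split(df$gene, df$mirna), unique)
}
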