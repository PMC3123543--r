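#' Pipeline configuration with published defaults
#'
#' Collects every tunable of the pipeline in one object. Defaults are the
#' published analysis settings: background floor 32, DE screen at
#' `q <= 0.10` and `|FC| >= 1.2`, 3 PLS components, 1000 bootstrap
#' replicates, significance at `q <= 0.3`, 1000 permutation simulations.
#'
#' @param floor Background floor for [floor_and_log2()].
#' @param q_cutoff,fc_cutoff DE screen cutoffs.
#' @param variance_mode t-test variance model (`"welch"` or `"pooled"`).
#' @param ncomp PLS latent components.
#' @param bootstrap_B Bootstrap replicates per pair.
#' @param fdr_threshold Significance q-value cutoff.
#' @param n_simulations Derangement simulations for the false detection
#'   rate.
#' @param correlation_kind `"pearson"` or `"spearman"` for the baseline.
#' @param direction `"down_up"` (default: down-miRNAs vs up-mRNAs, the
#'   inverse-regulation pairing) or `"up_down"` for the mirror analysis.
#' @param seed Master RNG seed.
#' @return A `RunConfig` list.
#' @export
run_config <- function(floor = 32, q_cutoff = 0.10, fc_cutoff = 1.2,
                       variance_mode = "welch", ncomp = 3L,
                       bootstrap_B = 1000L, fdr_threshold = 0.3,
                       n_simulations = 1000L, correlation_kind = "pearson",
                       direction = c("down_up", "up_down"), seed = 1L) {
  direction <- match.arg(direction)
  structure(list(
    floor = floor, q_cutoff = q_cutoff, fc_cutoff = fc_cutoff,
    variance_mode = variance_mode, ncomp = as.integer(ncomp),
    bootstrap_B = as.integer(bootstrap_B), fdr_threshold = fdr_threshold,
    n_simulations = as.integer(n_simulations),
    correlation_kind = correlation_kind, direction = direction,
    seed = as.integer(seed)
  ), class = "RunConfig")
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [run_config()].
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key: '%s'", bad[1L])
  do.call(run_config, vals)
}

#' Write a `RunConfig` (or run manifest) as YAML
#'
#' @param config A `RunConfig` or plain named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Serialize an association matrix as TSV
#'
#' Rows are mRNAs, columns miRNAs, plus a leading `intercept` column;
#' full-precision numbers so the matrix round-trips exactly.
#'
#' @param assoc An `AssociationMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(assoc, path) {
  stopifnot(inherits(assoc, "AssociationMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("mrna_id", "intercept", assoc$mirna_ids),
                   collapse = "\t"), con)
  for (i in seq_along(assoc$mrna_ids)) {
    writeLines(paste(c(assoc$mrna_ids[i],
                       sprintf("%.17g", c(assoc$intercepts[i],
                                          assoc$beta[i, ]))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an association matrix written by [write_association_matrix()]
#'
#' @param path File path.
#' @return An `AssociationMatrix`.
#' @export
read_association_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  beta <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(beta) <- df[[1L]]
  intercepts <- df[[2L]]
  names(intercepts) <- df[[1L]]
  structure(list(beta = beta, intercepts = intercepts,
                 mirna_ids = colnames(beta), mrna_ids = df[[1L]]),
            class = "AssociationMatrix")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full target-prediction pipeline
#'
#' End to end: read the two expression tables and the annotation, floor and
#' log2-transform, pair the blocks, screen both blocks for differential
#' expression, select the down-regulated miRNAs and up-regulated mRNAs (or
#' the mirror pairing), run the PLS + bootstrap association test, and build
#' and export the bipartite network. All stage outputs, a run manifest
#' (configuration + package version) and a log are written to `out_dir`.
#' Any stage failure aborts with an error naming the stage.
#'
#' @param mirna_path,mrna_path Paths to raw-intensity expression TSVs.
#' @param annotation_path Path to the `sample_id<TAB>group` TSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`paired`,
#'   `de_mirna`, `de_mrna`, `prediction`, `network`) and `paths` of all
#'   written files.
#' @export
run_pipeline <- function(mirna_path, mrna_path, annotation_path, out_dir,
                         config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("plstarget %s | seed %d", as.character(utils::packageVersion("plstarget")),
      config$seed)
  inputs <- stage("de", {
    ann <- read_sample_annotation(annotation_path)
    mirna <- floor_and_log2(read_expression_table(mirna_path), config$floor)
    mrna <- floor_and_log2(read_expression_table(mrna_path), config$floor)
    pair_blocks(mirna, mrna, ann)
  })
  de <- stage("de", {
    list(mirna = select_differential(inputs$mirna, inputs$annotation,
                                     config$q_cutoff, config$fc_cutoff,
                                     config$variance_mode),
         mrna = select_differential(inputs$mrna, inputs$annotation,
                                    config$q_cutoff, config$fc_cutoff,
                                    config$variance_mode))
  })
  mirna_dir <- if (config$direction == "down_up") "down" else "up"
  mrna_dir <- if (config$direction == "down_up") "up" else "down"
  sel_mirnas <- de$mirna$gene_id[de$mirna$direction == mirna_dir]
  sel_mrnas <- de$mrna$gene_id[de$mrna$direction == mrna_dir]
  say("DE screen: %d %s-regulated miRNAs, %d %s-regulated mRNAs selected",
      length(sel_mirnas), mirna_dir, length(sel_mrnas), mrna_dir)

  pred <- stage("predict", {
    if (!length(sel_mirnas) || !length(sel_mrnas)) {
      stopf("no %s-regulated miRNAs or no %s-regulated mRNAs survive the screen",
            mirna_dir, mrna_dir)
    }
    run_target_prediction(inputs, sel_mirnas, sel_mrnas,
                          ncomp = config$ncomp, B = config$bootstrap_B,
                          fdr_threshold = config$fdr_threshold,
                          rng_seed = config$seed)
  })
  say("predict: %d of %d pairs significant at q <= %g",
      nrow(pred$significant_pairs), nrow(pred$tests), config$fdr_threshold)

  net <- stage("network", build_bipartite_network(pred$significant_pairs))
  say("network: %d nodes, %d edges", net$n_nodes, net$n_edges)

  paths <- stage("write", {
    p <- c(de_mirna = file.path(out_dir, "de_mirna.tsv"),
           de_mrna = file.path(out_dir, "de_mrna.tsv"),
           associations = file.path(out_dir, "associations.tsv"),
           tests = file.path(out_dir, "pair_tests.tsv"),
           significant = file.path(out_dir, "significant_pairs.tsv"),
           targets = file.path(out_dir, "targets_by_mirna.tsv"),
           sif = file.path(out_dir, "network.sif"),
           graphml = file.path(out_dir, "network.graphml"),
           edges = file.path(out_dir, "network_edges.tsv"),
           manifest = file.path(out_dir, "run_manifest.yaml"))
    de_head <- sprintf("# variance_mode: %s", config$variance_mode)
    writeLines(c(de_head, readr_format(de$mirna)), p[["de_mirna"]])
    writeLines(c(de_head, readr_format(de$mrna)), p[["de_mrna"]])
    write_association_matrix(pred$associations, p[["associations"]])
    write_tsv(pred$tests, p[["tests"]])
    write_tsv(pred$significant_pairs, p[["significant"]])
    write_tsv(targets_by_mirna(pred$significant_pairs), p[["targets"]])
    export_network(net, p[["sif"]], "sif")
    export_network(net, p[["graphml"]], "graphml")
    export_network(net, p[["edges"]], "tsv")
    manifest <- c(unclass(config),
                  list(package_version =
                         as.character(utils::packageVersion("plstarget")),
                       inputs = list(mirna = mirna_path, mrna = mrna_path,
                                     annotation = annotation_path)))
    yaml::write_yaml(manifest, p[["manifest"]])
    p
  })
  say("done: outputs in %s", out_dir)
  invisible(list(paired = inputs, de_mirna = de$mirna, de_mrna = de$mrna,
                 prediction = pred, network = net, paths = paths))
}

# data frame -> header + tab-joined body lines
readr_format <- function(df) {
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  c(paste(names(df), collapse = "\t"), body)
}
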