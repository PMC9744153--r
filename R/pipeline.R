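#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. All outputs are
#' deterministic given the configuration and seed.
#'
#' @param registry \code{"default"} or the path of a registry file readable
#'   by \code{\link{read_taxon_registry}}.
#' @param dominance_threshold dominance threshold for the CST rule table
#'   (default 0.50, inclusive).
#' @param rarefy_depth rarefaction depth for counts-mode input (default
#'   80000, the depth of the amplicon pipeline this mirrors); \code{NULL}
#'   skips rarefaction.
#' @param distance beta-diversity dissimilarity, \code{"bray_curtis"} or
#'   \code{"euclidean"}.
#' @param n_perm PERMANOVA permutation count (default 999).
#' @param correlation_pairs list of variable-name pairs for
#'   \code{\link{correlate_groups}}.
#' @param seed integer seed used for every stochastic stage.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(registry = "default", dominance_threshold = 0.5,
                            rarefy_depth = 80000,
                            distance = c("bray_curtis", "euclidean"),
                            n_perm = 999,
                            correlation_pairs = default_correlation_pairs(),
                            seed = 1L) {
  distance <- match.arg(distance)
  structure(list(registry = registry,
                 dominance_threshold = dominance_threshold,
                 rarefy_depth = rarefy_depth, distance = distance,
                 n_perm = n_perm, correlation_pairs = correlation_pairs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# TSV writer with a commented provenance header
write_tsv_prov <- function(df, path, seed) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# vagcst %s\tseed=%d",
                     as.character(utils::packageVersion("vagcst")), seed),
             con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes read -> (optional rarefy) -> relative abundance -> CST
#' classification -> per-cohort summaries -> Shannon / Bray-Curtis /
#' PERMANOVA / pairwise Kruskal-Wallis -> correlation battery, and writes
#' the result bundle (assignments, summaries, matrices, test results and a
#' run manifest) to \code{out_dir}. Running twice with the same inputs,
#' configuration and seed produces byte-identical files.
#'
#' @param table an \code{abundance_table} or the path of a TSV taxa table.
#' @param metadata a metadata data frame (\code{sample_id}, \code{group}) or
#'   the path of a two-column TSV.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory, created if needed; \code{NULL} skips
#'   writing and just returns the bundle.
#' @return Invisibly, a list with elements \code{assignments},
#'   \code{summary}, \code{shannon}, \code{kruskal_wallis},
#'   \code{bray_curtis}, \code{permanova}, \code{correlations},
#'   \code{manifest}.
#' @export
run_pipeline <- function(table, metadata, config = pipeline_config(),
                         out_dir = NULL) {
  registry <- if (identical(config$registry, "default")) {
    default_registry()
  } else {
    read_taxon_registry(config$registry)
  }
  input_files <- character()
  if (is.character(table)) {
    input_files <- c(input_files, table = table)
    table <- read_abundance_table(table, registry)
  }
  if (is.character(metadata)) {
    input_files <- c(input_files, metadata = metadata)
    metadata <- read_sample_metadata(metadata)
  }
  missing <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(missing)) {
    stop_vagcst("metadata missing for sample(s): ",
                paste(missing, collapse = ", "))
  }

  if (table$mode == "counts") {
    if (!is.null(config$rarefy_depth)) {
      table <- rarefy_counts(table, depth = config$rarefy_depth,
                             seed = config$seed)
    }
    table <- to_relative_abundance(table)
  }
  metadata <- metadata[metadata$sample_id %in% sample_ids(table), ]

  cfg <- classifier_config(dominance_threshold = config$dominance_threshold)
  assignments <- classify_cohort(table, metadata, registry, cfg)
  summary <- summarize_cst_counts(assignments)

  shannon <- shannon_diversity(table)
  kw <- pairwise_group_test(shannon, metadata)
  bc <- bray_curtis_matrix(table)
  d <- if (config$distance == "bray_curtis") {
    bc
  } else {
    as.matrix(stats::dist(table$values))
  }
  pmv <- permanova(d, metadata, n_perm = config$n_perm, seed = config$seed)
  correlations <- correlate_groups(table, config$correlation_pairs, registry,
                                   seed = config$seed)

  manifest <- list(
    package = "vagcst",
    version = as.character(utils::packageVersion("vagcst")),
    seed = config$seed,
    config = list(registry = config$registry,
                  dominance_threshold = config$dominance_threshold,
                  rarefy_depth = config$rarefy_depth,
                  distance = config$distance, n_perm = config$n_perm),
    n_samples = nrow(table$values),
    n_taxa = ncol(table$values),
    input_md5 = if (length(input_files)) {
      as.list(stats::setNames(unname(tools::md5sum(input_files)),
                              names(input_files)))
    } else {
      NULL
    })

  bundle <- list(assignments = assignments, summary = summary,
                 shannon = shannon, kruskal_wallis = kw, bray_curtis = bc,
                 permanova = pmv, correlations = correlations,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    s <- config$seed
    write_tsv_prov(as.data.frame(assignments), file.path(out_dir, "assignments.tsv"), s)
    counts <- summary$counts
    write_tsv_prov(data.frame(cst = rownames(counts), counts,
                              check.names = FALSE),
                   file.path(out_dir, "cst_summary.tsv"), s)
    write_tsv_prov(data.frame(sample_id = names(shannon), shannon = shannon),
                   file.path(out_dir, "shannon.tsv"), s)
    write_tsv_prov(kw, file.path(out_dir, "kruskal_wallis.tsv"), s)
    write_tsv_prov(data.frame(sample_id = rownames(bc), bc,
                              check.names = FALSE),
                   file.path(out_dir, "bray_curtis.tsv"), s)
    write_tsv_prov(pmv, file.path(out_dir, "permanova.tsv"), s)
    write_tsv_prov(correlations, file.path(out_dir, "correlations.tsv"), s)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}
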