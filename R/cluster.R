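#' De-novo clustering of compositions by complete linkage
#'
#' Agglomerates samples with complete-linkage hierarchical clustering on
#' Bray-Curtis (default) or Euclidean distances, the procedure under which
#' the extended CST scheme's clusters were originally found. The tree can be
#' cut either at a requested number of clusters \code{k} or at a merge
#' height \code{cut_height}. Each cluster is additionally mapped to a CST by
#' majority vote over the per-sample rule-based labels.
#'
#' @param table an \code{abundance_table} in relative mode with >= 2 samples.
#' @param distance \code{"bray_curtis"} (default) or \code{"euclidean"}.
#' @param k number of clusters to cut the dendrogram into (1..n samples).
#' @param cut_height alternative to \code{k}: cut at this merge height.
#' @param registry,config passed to \code{\link{assign_cst}} for the
#'   cluster-to-CST majority mapping.
#' @return A list of class \code{cst_clustering}: \code{labels} (named
#'   integer cluster per sample), \code{hclust} (the merge tree),
#'   \code{newick} (Newick text export of the dendrogram),
#'   \code{cluster_cst} (majority CST per cluster) and \code{distance}.
#' @export
cluster_compositions <- function(table, distance = c("bray_curtis",
                                                     "euclidean"),
                                 k = NULL, cut_height = NULL,
                                 registry = default_registry(),
                                 config = classifier_config()) {
  distance <- match.arg(distance)
  if (table$mode != "relative") {
    stop_vagcst("cluster_compositions expects a relative-mode table")
  }
  n <- nrow(table$values)
  if (n < 2L) stop_vagcst("clustering needs at least 2 samples")
  if (!is.null(k) && (k < 1L || k > n)) {
    stop_vagcst("k must be between 1 and the number of samples (", n, ")")
  }
  d <- if (distance == "bray_curtis") {
    vegan::vegdist(table$values, method = "bray")
  } else {
    stats::dist(table$values, method = "euclidean")
  }
  hc <- stats::hclust(d, method = "complete")
  labels <- if (!is.null(k)) {
    stats::cutree(hc, k = k)
  } else if (!is.null(cut_height)) {
    stats::cutree(hc, h = cut_height)
  } else {
    stats::cutree(hc, k = min(8L, n))
  }
  assignments <- classify_cohort(table, registry = registry, config = config)
  per_sample <- stats::setNames(assignments$cst, assignments$sample_id)
  cluster_cst <- vapply(split(names(labels), labels), function(ids) {
    tab <- sort(table(per_sample[ids]), decreasing = TRUE)
    names(tab)[1L]
  }, "")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(labels = labels, hclust = hc, newick = newick,
                 cluster_cst = cluster_cst, distance = distance),
            class = "cst_clustering")
}

#' @export
print.cst_clustering <- function(x, ...) {
  cat("<cst_clustering>", length(x$labels), "samples,",
      length(unique(x$labels)), "clusters (", x$distance,
      ", complete linkage)\n")
  print(x$cluster_cst)
  invisible(x)
}
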