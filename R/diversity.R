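#' Shannon diversity index of a composition
#'
#' \deqn{H = -\sum_{i: p_i > 0} p_i \log_b p_i}
#' computed over taxa with positive relative abundance. Base 2 (bits) is the
#' default, matching the amplicon pipeline convention this package mirrors;
#' natural log is available.
#'
#' @param composition named numeric vector of relative abundances summing
#'   to 1.
#' @param base \code{2} (bits, default) or \code{exp(1)} (nats).
#' @return A non-negative number, at most \code{log(base = base)} of the
#'   number of taxa present.
#' @export
shannon_index <- function(composition, base = 2) {
  check_composition(composition)
  as.numeric(vegan::diversity(matrix(composition, nrow = 1L),
                              index = "shannon", base = base))
}

#' Shannon index for every sample of a table
#'
#' @param table an \code{abundance_table} in relative mode.
#' @inheritParams shannon_index
#' @return Named numeric vector, one value per sample.
#' @export
shannon_diversity <- function(table, base = 2) {
  if (table$mode != "relative") {
    stop_vagcst("shannon_diversity expects a relative-mode table")
  }
  vegan::diversity(table$values, index = "shannon", base = base)
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' For normalized vectors \eqn{x, y}: \eqn{BC(x, y) = 1 - \sum_i \min(x_i,
#' y_i)}. Values lie in \[0, 1\] with a zero diagonal; Bray-Curtis is a
#' semimetric (the triangle inequality may fail).
#'
#' @param table an \code{abundance_table} in relative mode.
#' @return A symmetric numeric matrix with sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  if (table$mode != "relative") {
    stop_vagcst("bray_curtis_matrix expects a relative-mode table")
  }
  as.matrix(vegan::vegdist(table$values, method = "bray"))
}

#' Write a distance matrix as square TSV
#'
#' @param d symmetric matrix with sample-id dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Global and pairwise Kruskal-Wallis tests across cohort groups
#'
#' Runs the global Kruskal-Wallis rank-sum test over all groups plus one
#' test per group pair, with Benjamini-Hochberg adjustment across the
#' pairwise p-values.
#'
#' @param values numeric vector of per-sample values (e.g. Shannon indices),
#'   named by sample id or aligned with \code{meta}.
#' @param meta data frame with \code{sample_id}, \code{group}; every group
#'   needs >= 2 samples and >= 2 groups are required.
#' @return Data frame with columns \code{scope} (\code{"global"} or
#'   \code{"pair"}), \code{group_a}, \code{group_b}, \code{statistic},
#'   \code{p_value}, \code{adjusted_p}.
#' @export
pairwise_group_test <- function(values, meta) {
  if (!is.null(names(values))) {
    i <- match(meta$sample_id, names(values))
    if (any(is.na(i))) {
      stop_vagcst("values missing for sample(s): ",
                  paste(meta$sample_id[is.na(i)], collapse = ", "))
    }
    values <- values[i]
  } else if (length(values) != nrow(meta)) {
    stop_vagcst("values and metadata lengths differ")
  }
  grp <- factor(meta$group)
  sizes <- table(grp)
  if (length(sizes) < 2L) stop_vagcst("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop_vagcst("group(s) with fewer than 2 samples: ",
                paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  kw <- function(v, g) {
    if (stats::var(v) == 0) {
      list(statistic = 0, p.value = 1)  # all observations tied
    } else {
      t <- stats::kruskal.test(v, g)
      list(statistic = unname(t$statistic), p.value = t$p.value)
    }
  }
  g <- kw(values, grp)
  out <- data.frame(scope = "global", group_a = NA_character_,
                    group_b = NA_character_, statistic = g$statistic,
                    p_value = g$p.value)
  pairs <- utils::combn(levels(grp), 2L, simplify = FALSE)
  pr <- lapply(pairs, function(p) {
    sel <- grp %in% p
    t <- kw(values[sel], droplevels(grp[sel]))
    data.frame(scope = "pair", group_a = p[1L], group_b = p[2L],
               statistic = t$statistic, p_value = t$p.value)
  })
  pr <- do.call(rbind, pr)
  pr$adjusted_p <- stats::p.adjust(pr$p_value, method = "BH")
  out$adjusted_p <- out$p_value
  rbind(out, pr)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA of a dissimilarity matrix against the cohort grouping:
#' a pseudo-F statistic from between/within sums of squared dissimilarities,
#' with the p-value \eqn{(1 + \#\{F^{perm} \ge F^{obs}\}) / (1 + n_{perm})}
#' from free permutation of sample labels. Computation is delegated to
#' \code{vegan::adonis2}; the seed makes the permutation set reproducible.
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   \code{\link{bray_curtis_matrix}}) with sample-id dimnames.
#' @param meta data frame with \code{sample_id}, \code{group}; >= 2 groups,
#'   no singleton groups.
#' @param n_perm number of permutations (>= 99; default 999, giving a
#'   minimum attainable p of 0.001).
#' @param seed integer seed.
#' @return Data frame with one row: \code{statistic} (pseudo-F),
#'   \code{r_squared}, \code{p_value}, \code{n_permutations}.
#' @export
permanova <- function(d, meta, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop_vagcst("n_perm must be >= 99")
  d <- as.matrix(d)
  i <- match(rownames(d), meta$sample_id)
  if (any(is.na(i))) {
    stop_vagcst("metadata missing for sample(s): ",
                paste(rownames(d)[is.na(i)], collapse = ", "))
  }
  grp <- factor(meta$group[i])
  sizes <- table(grp)
  if (length(sizes) < 2L) stop_vagcst("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop_vagcst("singleton group(s): ",
                paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  df <- data.frame(group = grp)
  fit <- with_seed(seed,
                   vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                                  permutations = n_perm))
  data.frame(statistic = fit$F[1L], r_squared = fit$R2[1L],
             p_value = fit$`Pr(>F)`[1L], n_permutations = n_perm)
}
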