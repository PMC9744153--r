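#' Taxa-by-sample abundance tables
#'
#' An \code{abundance_table} wraps a samples x taxa numeric matrix together
#' with its mode: \code{"counts"} (non-negative integers, read counts) or
#' \code{"relative"} (each row a relative-abundance vector). Taxon names are
#' canonical registry names; sample ids are unique.
#'
#' @param values numeric matrix, samples as rows, taxa as columns, with
#'   rownames (sample ids) and colnames (canonical taxa).
#' @param mode \code{"counts"} or \code{"relative"}.
#' @return An object of class \code{abundance_table}.
#' @export
abundance_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      (nrow(values) > 0L && is.null(rownames(values)))) {
    stop_vagcst("abundance matrix needs sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_vagcst("duplicate sample ids in abundance table")
  }
  if (anyDuplicated(colnames(values))) {
    stop_vagcst("duplicate taxa in abundance table")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_vagcst("abundance table contains negative or non-finite values")
  }
  structure(list(values = values, mode = mode), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>", nrow(x$values), "samples x", ncol(x$values),
      "taxa, mode:", x$mode, "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

sample_ids <- function(table) rownames(table$values)
taxa_names <- function(table) colnames(table$values)

#' Read a taxa abundance table from a tab-separated file
#'
#' The file must have a header row. By default samples are rows and taxa are
#' columns; set \code{orientation = "taxa_as_rows"} for the transposed
#' layout. Taxon labels are canonicalized against the registry and columns
#' that collide after canonicalization (synonyms, species folded to genus)
#' are summed. By default mode is auto-detected: if every row sums to ~1 or
#' ~100 the table is treated as relative abundances (percentages are divided
#' by 100), otherwise as counts; \code{mode} overrides the detection (useful
#' for truncated top-N percentage tables whose rows sum below 100). An
#' \code{"Unassigned"} column is kept as a taxon.
#'
#' @param path file path to a TSV table.
#' @param registry a \code{taxon_registry}; defaults to
#'   \code{\link{default_registry}()}.
#' @param orientation \code{"samples_as_rows"} (default) or
#'   \code{"taxa_as_rows"}.
#' @param mode \code{"auto"} (default), \code{"counts"}, \code{"relative"}
#'   (fractions) or \code{"percent"} (relative, divided by 100 on read).
#' @return An \code{\link{abundance_table}}.
#' @export
read_abundance_table <- function(path, registry = default_registry(),
                                 orientation = c("samples_as_rows",
                                                 "taxa_as_rows"),
                                 mode = c("auto", "counts", "relative",
                                          "percent")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                          fileEncoding = "UTF-8")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (orientation == "taxa_as_rows") m <- t(m)
  if (any(is.na(m))) stop_vagcst("abundance table contains missing values")
  if (any(m < 0)) stop_vagcst("abundance table contains negative values")
  if (anyDuplicated(rownames(m))) {
    stop_vagcst("duplicate sample ids in abundance table")
  }
  colnames(m) <- canonical_names(colnames(m), registry)
  if (anyDuplicated(colnames(m))) {
    # synonyms folded onto one canonical taxon: sum their columns
    m <- t(rowsum(t(m), group = colnames(m), reorder = FALSE))
  }
  if (mode == "auto") {
    rs <- rowSums(m)
    mode <- "counts"
    if (all(abs(rs - 1) < 0.1)) {
      mode <- "relative"
    } else if (all(abs(rs - 100) < 10)) {
      mode <- "percent"
    }
  }
  if (mode == "percent") {
    m <- m / 100
    mode <- "relative"
  }
  abundance_table(m, mode)
}

#' Write an abundance table as TSV
#'
#' Samples as rows, taxa as columns, UTF-8, Unix newlines. Counts are
#' written as integers; relative abundances at full precision.
#'
#' @param table an \code{abundance_table}.
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  m <- table$values
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read sample metadata (sample id to cohort group)
#'
#' Two-column TSV with header: \code{sample_id}, \code{group}.
#'
#' @param path file path.
#' @return Data frame with character columns \code{sample_id}, \code{group}.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop_vagcst("metadata must have columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(df$sample_id)) stop_vagcst("duplicate sample ids in metadata")
  df[, c("sample_id", "group")]
}

#' Convert counts to relative abundances
#'
#' @param table an \code{abundance_table} in counts mode.
#' @return The table with each row divided by its row total, mode
#'   \code{"relative"}.
#' @export
to_relative_abundance <- function(table) {
  if (table$mode != "counts") {
    stop_vagcst("to_relative_abundance expects a counts-mode table")
  }
  tot <- rowSums(table$values)
  if (any(tot <= 0)) {
    stop_vagcst("sample(s) with zero total counts: ",
                paste(rownames(table$values)[tot <= 0], collapse = ", "))
  }
  abundance_table(table$values / tot, "relative")
}

#' Rarefy count samples to a common sequencing depth
#'
#' Each sample with at least \code{depth} total reads is subsampled without
#' replacement (multivariate hypergeometric) to exactly \code{depth} reads;
#' samples below the depth are dropped with a warning. The draw is seeded
#' and reproducible.
#'
#' @param table an \code{abundance_table} in counts mode.
#' @param depth target depth (reads per sample), >= 1. The study pipeline
#'   this mirrors used 80,000.
#' @param seed integer seed.
#' @return A counts-mode \code{abundance_table} whose row sums all equal
#'   \code{depth}.
#' @export
rarefy_counts <- function(table, depth = 80000, seed = 1L) {
  if (table$mode != "counts") stop_vagcst("rarefy_counts expects counts mode")
  if (depth < 1) stop_vagcst("depth must be >= 1")
  tot <- rowSums(table$values)
  keep <- tot >= depth
  if (!any(keep)) {
    stop_vagcst("all samples are below the rarefaction depth ", depth)
  }
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(table$values)[!keep], collapse = ", "),
            call. = FALSE)
  }
  m <- table$values[keep, , drop = FALSE]
  # rrarefy warns heuristically when the smallest count exceeds 1; the
  # counts mode is already validated here
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(round(m), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  dimnames(out) <- dimnames(m)
  abundance_table(out, "counts")
}

#' Per-group mean relative-abundance profiles
#'
#' Computes the arithmetic mean relative-abundance vector of each cohort
#' group, plus an "overall" profile. Following the convention of the study
#' tables this reproduces, the overall profile is the \emph{unweighted}
#' arithmetic mean of the group profiles, not the pooled per-sample mean
#' (set \code{overall = "pooled"} for the latter).
#'
#' @param table an \code{abundance_table} in relative mode.
#' @param meta data frame with columns \code{sample_id}, \code{group}
#'   covering every sample in the table.
#' @param overall \code{"group_mean"} (default) or \code{"pooled"}.
#' @return A list with \code{groups} (named list of compositions, i.e. named
#'   numeric vectors) and \code{overall} (composition).
#' @export
group_mean_profile <- function(table, meta,
                               overall = c("group_mean", "pooled")) {
  overall <- match.arg(overall)
  if (table$mode != "relative") {
    stop_vagcst("group_mean_profile expects a relative-mode table")
  }
  ids <- sample_ids(table)
  i <- match(ids, meta$sample_id)
  if (any(is.na(i))) {
    stop_vagcst("metadata missing for sample(s): ",
                paste(ids[is.na(i)], collapse = ", "))
  }
  grp <- meta$group[i]
  if (any(!nzchar(grp)) || any(is.na(grp))) stop_vagcst("empty group label")
  groups <- lapply(split(seq_along(ids), grp), function(rows) {
    colMeans(table$values[rows, , drop = FALSE])
  })
  ov <- if (overall == "group_mean") {
    Reduce(`+`, groups) / length(groups)
  } else {
    colMeans(table$values)
  }
  list(groups = groups, overall = ov)
}

#' Total relative abundance of a taxon panel in a profile
#'
#' Sums the relative abundances of the panel members present in the profile;
#' absent members contribute zero. Panel names are canonicalized against the
#' registry, so e.g. \code{"Escherichia"} matches an
#' \code{"Escherichia-Shigella"} column.
#'
#' @param profile a composition (named numeric vector of relative abundances).
#' @param panel character vector of taxon names.
#' @param registry optional \code{taxon_registry} used to canonicalize
#'   \code{panel}; \code{NULL} to match names verbatim.
#' @return A single number in \[0, 1\].
#' @export
panel_total <- function(profile, panel, registry = NULL) {
  if (length(panel) == 0L) return(0)
  if (!is.null(registry)) panel <- canonical_names(panel, registry, warn = FALSE)
  sum(profile[names(profile) %in% panel])
}
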