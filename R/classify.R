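#' Extended community state type labels
#'
#' The twelve labels of the extended CST scheme: the classic
#' Lactobacillus-dominant types (I = \emph{L. crispatus}, II =
#' \emph{L. gasseri}, III = \emph{L. iners}, V = \emph{L. jensenii}), the
#' polymicrobial CST IV subtypes (IV-A: \emph{G. vaginalis} on top below the
#' dominance threshold; IV-B: \emph{Prevotella} on top below threshold;
#' IV-C: any other taxon on top below threshold), the non-Lactobacillus
#' dominance types (VI: \emph{G. vaginalis}; VII: \emph{Prevotella}; VIII:
#' a THPP genus; IX: any other taxon), and UNRESOLVED (a non-canonical
#' \emph{Lactobacillus} species at or above threshold).
#'
#' @return Character vector of the labels in canonical order.
#' @export
cst_levels <- function() {
  c("I", "II", "III", "IV-A", "IV-B", "IV-C", "V", "VI", "VII", "VIII", "IX",
    "UNRESOLVED")
}

# the four species that define CST I / II / III / V
canonical_four <- c(I = "Lactobacillus crispatus",
                    II = "Lactobacillus gasseri",
                    III = "Lactobacillus iners",
                    V = "Lactobacillus jensenii")

#' Classifier configuration
#'
#' @param dominance_threshold fraction in (0, 1]; a sample is "dominated"
#'   when its top taxon's relative abundance is \emph{at or above} this
#'   value (inclusive). Default 0.50, the criterion "equal or greater than
#'   50\%" under which the extended scheme names a CST after its dominant
#'   organism.
#' @param tie_break ordered group priority used when two taxa tie exactly at
#'   the maximum relative abundance; within a group ties break
#'   alphabetically.
#' @param fold_unresolved_into optional CST label to assign instead of
#'   \code{"UNRESOLVED"} when a non-canonical \emph{Lactobacillus} species
#'   dominates.
#' @return A list of class \code{classifier_config}.
#' @export
classifier_config <- function(dominance_threshold = 0.5,
                              tie_break = c("LACTOBACILLUS", "GARDNERELLA",
                                            "PREVOTELLA", "THPP", "OTHER"),
                              fold_unresolved_into = NULL) {
  if (!is.numeric(dominance_threshold) || length(dominance_threshold) != 1L ||
      dominance_threshold <= 0 || dominance_threshold > 1) {
    stop_vagcst("dominance_threshold must be a single value in (0, 1]")
  }
  if (!setequal(tie_break, c("LACTOBACILLUS", "GARDNERELLA", "PREVOTELLA",
                             "THPP", "OTHER"))) {
    stop_vagcst("tie_break must order the five functional groups")
  }
  if (!is.null(fold_unresolved_into) &&
      !fold_unresolved_into %in% cst_levels()) {
    stop_vagcst("fold_unresolved_into must be a CST label")
  }
  structure(list(dominance_threshold = dominance_threshold,
                 tie_break = tie_break,
                 fold_unresolved_into = fold_unresolved_into),
            class = "classifier_config")
}

#' Assign an extended community state type to one sample
#'
#' Applies the dominance rule table to a normalized composition. Let
#' \code{top} be the taxon with maximum relative abundance \code{r} and
#' \code{thr} the dominance threshold (default 0.50, inclusive):
#' \itemize{
#'   \item \code{r >= thr}, top is \emph{L. crispatus} / \emph{L. gasseri} /
#'     \emph{L. iners} / \emph{L. jensenii}: CST I / II / III / V.
#'   \item \code{r >= thr}, top is \emph{Gardnerella vaginalis}: CST VI.
#'   \item \code{r >= thr}, top in the PREVOTELLA group: CST VII.
#'   \item \code{r >= thr}, top in the THPP group: CST VIII.
#'   \item \code{r >= thr}, any other taxon: CST IX (a non-canonical
#'     \emph{Lactobacillus} species instead yields UNRESOLVED).
#'   \item \code{r < thr}, top is \emph{G. vaginalis}: CST IV-A.
#'   \item \code{r < thr}, top in PREVOTELLA: CST IV-B.
#'   \item \code{r < thr} otherwise (including a sub-threshold
#'     \emph{Lactobacillus} top): CST IV-C.
#' }
#' Exact ties at the maximum are broken by the configured group priority,
#' then alphabetically, and noted in the rationale.
#'
#' @param composition named numeric vector of relative abundances summing to
#'   1 (canonical taxon names).
#' @param registry a \code{taxon_registry}.
#' @param config a \code{\link{classifier_config}}.
#' @param sample_id optional id recorded in the result.
#' @return A list with fields \code{sample_id}, \code{cst},
#'   \code{dominant_taxon}, \code{dominant_ra} and \code{rationale}.
#' @examples
#' reg <- default_registry()
#' x <- c("Lactobacillus gasseri" = 0.52, "Lactobacillus iners" = 0.43,
#'        "Atopobium" = 0.05)
#' assign_cst(x, reg)$cst  # "II"
#' @export
assign_cst <- function(composition, registry = default_registry(),
                       config = classifier_config(), sample_id = NA_character_) {
  check_composition(composition)
  thr <- config$dominance_threshold

  r <- max(composition)
  tied <- names(composition)[composition >= r - 1e-12]
  tie_note <- ""
  if (length(tied) > 1L) {
    grps <- vapply(tied, group_of, "", registry = registry)
    pri <- match(grps, config$tie_break)
    ord <- order(pri, tied)
    top <- tied[ord[1L]]
    tie_note <- paste0("; tie among {", paste(sort(tied), collapse = ", "),
                       "} broken by group priority")
  } else {
    top <- tied
  }
  grp <- group_of(top, registry)
  dominant <- r >= thr

  label <- if (dominant) {
    if (top %in% canonical_four) {
      names(canonical_four)[match(top, canonical_four)]
    } else if (grp == "LACTOBACILLUS") {
      config$fold_unresolved_into %||% "UNRESOLVED"
    } else if (top == "Gardnerella vaginalis") {
      "VI"
    } else if (grp == "PREVOTELLA") {
      "VII"
    } else if (grp == "THPP") {
      "VIII"
    } else {
      "IX"
    }
  } else {
    if (top == "Gardnerella vaginalis") {
      "IV-A"
    } else if (grp == "PREVOTELLA") {
      "IV-B"
    } else {
      "IV-C"
    }
  }

  rationale <- sprintf(
    "%s: top taxon %s (group %s) RA=%.4f %s threshold %.2f%s",
    if (dominant) "dominance" else "polymicrobial",
    top, grp, r, if (dominant) ">=" else "<", thr, tie_note)

  list(sample_id = sample_id, cst = label, dominant_taxon = top,
       dominant_ra = r, rationale = rationale)
}

#' Classify every sample of a cohort
#'
#' @param table an \code{abundance_table} in relative mode.
#' @param meta optional metadata data frame (\code{sample_id}, \code{group});
#'   when given, the group is carried into the result.
#' @param registry a \code{taxon_registry}.
#' @param config a \code{\link{classifier_config}}.
#' @return A data frame of class \code{cst_assignments} with columns
#'   \code{sample_id}, \code{group}, \code{cst}, \code{dominant_taxon},
#'   \code{dominant_ra}, \code{rationale}; one row per sample, deterministic
#'   given the inputs.
#' @export
classify_cohort <- function(table, meta = NULL,
                            registry = default_registry(),
                            config = classifier_config()) {
  if (table$mode != "relative") {
    stop_vagcst("classify_cohort expects a relative-mode table")
  }
  ids <- sample_ids(table)
  taxa <- colnames(table$values)
  rows <- lapply(ids, function(id) {
    comp <- stats::setNames(table$values[id, ], taxa)  # keep names at 1 taxon
    res <- tryCatch(
      assign_cst(comp, registry, config, sample_id = id),
      error = function(e) {
        stop_vagcst("sample '", id, "': ", conditionMessage(e))
      })
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(sample_id = character(), cst = character(),
               dominant_taxon = character(), dominant_ra = numeric(),
               rationale = character())
  out$group <- if (is.null(meta)) {
    rep(NA_character_, nrow(out))
  } else {
    meta$group[match(out$sample_id, meta$sample_id)]
  }
  out <- out[, c("sample_id", "group", "cst", "dominant_taxon",
                 "dominant_ra", "rationale")]
  rownames(out) <- NULL
  class(out) <- c("cst_assignments", "data.frame")
  out
}

#' @export
print.cst_assignments <- function(x, ...) {
  cat("<cst_assignments>", nrow(x), "samples\n")
  print(table(factor(x$cst, levels = cst_levels())))
  invisible(x)
}

#' Tally CST assignments per cohort group and overall
#'
#' @param assignments a \code{cst_assignments} data frame.
#' @param meta optional metadata; defaults to the \code{group} column of
#'   \code{assignments}.
#' @return A list of class \code{cst_summary} with \code{counts} and
#'   \code{percentages} matrices (CST x group, plus an \code{overall}
#'   column) and \code{n} (group sizes).
#' @export
summarize_cst_counts <- function(assignments, meta = NULL) {
  grp <- if (!is.null(meta)) {
    meta$group[match(assignments$sample_id, meta$sample_id)]
  } else {
    assignments$group
  }
  if (all(is.na(grp))) grp <- rep("all", nrow(assignments))
  cst <- factor(assignments$cst, levels = cst_levels())
  counts <- table(cst, group = grp)
  counts <- cbind(counts, overall = rowSums(counts))
  n <- colSums(counts)
  pct <- sweep(counts, 2L, n, `/`) * 100
  structure(list(counts = counts, percentages = pct, n = n),
            class = "cst_summary")
}

#' @export
print.cst_summary <- function(x, ...) {
  cat("<cst_summary> counts (columns: groups + overall)\n")
  print(x$counts[rowSums(x$counts) > 0, , drop = FALSE])
  invisible(x)
}
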