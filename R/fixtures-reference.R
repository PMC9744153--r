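# The built-in reference cohort: 151 cluster-description constraints for a
# five-cohort (AA, AC, AI, AK, CG) vaginal microbiome study. Each entry
# states the numeric relative-abundance assertions of one observed cluster
# description and how many samples of each cohort realized it. Relational
# descriptions ("X more abundant than Y, Z, ...") are encoded as numeric
# ranges that preserve the stated dominance order.

#' Reference cohort cluster-description constraints
#'
#' The 151-sample, five-cohort reference set of cluster descriptions from
#' which the extended CST scheme was defined, encoded as
#' \code{\link{fixture_constraint}} objects plus per-cohort sample counts.
#' \code{reference_cohort_fixtures} expands them into 151 unlabeled
#' compositions with cohort metadata; the CST labels are recoverable only by
#' running \code{\link{assign_cst}}.
#'
#' @return \code{reference_cohort_constraints()}: a list of entries, each
#'   with \code{constraint} (a \code{fixture_constraint}) and \code{n} (named
#'   per-cohort counts).
#' @export
reference_cohort_constraints <- function() {
  a <- ra_assert
  row <- function(n, ...) list(n = n, constraint = fixture_constraint(...))
  n <- function(...) c(...)
  Lc <- "Lactobacillus crispatus"; Li <- "Lactobacillus iners"
  Lg <- "Lactobacillus gasseri"; Gv <- "Gardnerella vaginalis"
  Pv <- "Prevotella"; CLV <- "Candidatus Lachnocurva vaginae"

  list(
    # --- L. crispatus predominant (RA >= 50%) ---
    row(n(AA = 5, AC = 1, AK = 2, CG = 4), a(Lc, "gt", 98.9)),
    row(n(AA = 2), a(Lc, "gt", 97), a(Pv, "gt", 0.5, 1.5)),
    row(n(CG = 1), a(Lc, "gt", 97), a(Gv, "gt", 2.0, 2.8)),
    row(n(AA = 5, AI = 2, AK = 1), a(Lc, "gt", 92), a(Li, "gt", 0.5, 4)),
    row(n(AI = 1), a(Lc, "gt", 66, 69), a(Li, "gt", 30)),
    row(n(AC = 1), a(Lc, "ge", 55, 59), a(Li, "eq", 40)),
    row(n(AI = 1), a(Lc, "gt", 90), a(Li, "gt", 4, 6), a("Corynebacterium", "gt", 1.0, 2)),
    row(n(AA = 2), a(Lc, "gt", 57, 62), a("Atopobium", "gt", 20, 25), a(Gv, "gt", 14, 16)),
    row(n(AI = 1), a(Lc, "gt", 86), a(Gv, "gt", 5.0, 6), a("Streptococcus", "gt", 2.5, 3.5),
        a("Staphylococcus", "gt", 1.6, 2.2)),
    row(n(CG = 1), a(Lc, "gt", 86, 90), a(Li, "gt", 3.0, 5)),
    row(n(AI = 1), a(Lc, "gt", 80, 85), a("Bifidobacterium", "gt", 6.3, 6.9),
        a("Enterococcus", "gt", 5.2, 6)),
    row(n(AI = 1), a(Lc, "gt", 80, 85), a("Bifidobacterium", "gt", 6.3, 6.9),
        a("Streptococcus", "gt", 3.1, 4)),
    row(n(CG = 1), a(Lc, "ge", 80, 86), a(Gv, "gt", 8.0, 10)),

    # --- L. gasseri predominant ---
    row(n(AI = 1), a(Lg, "eq", 52), a(Li, "eq", 43)),

    # --- L. iners predominant ---
    row(n(AA = 2, AC = 2, AI = 1, AK = 6, CG = 1), a(Li, "ge", 98)),
    row(n(AA = 3, AK = 1, CG = 1), a(Li, "gt", 90), a(Lc, "gt", 1.5, 4)),
    row(n(AA = 2), a(Li, "range", 60, 75), a(Lc, "gt", 24, 28)),
    row(n(AA = 4), a(Li, "gt", 80), a(Lg, "range", 2.8, 17)),
    row(n(AI = 3, CG = 1), a(Li, "ge", 80, 92)),
    row(n(AI = 1), a(Li, "eq", 72), a("Unassigned", "eq", 25)),
    row(n(AC = 1, CG = 4), a(Li, "gt", 80), a(Gv, "range", 4.0, 10)),
    row(n(AA = 2, CG = 1), a(Li, "gt", 55, 62), a(Gv, "gt", 25, 30),
        a("Atopobium", "range", 1, 6)),
    row(n(AK = 1, CG = 1), a(Li, "gt", 50, 60), a("Staphylococcus", "range", 3, 10),
        a("Streptococcus", "range", 3, 10), a("Enterococcus", "range", 3, 10)),

    # --- polymicrobial, G. vaginalis on top below 50% ---
    row(n(AK = 1), a(Gv, "eq", 44), a("Atopobium", "eq", 32), a("Veillonella", "eq", 11)),
    row(n(AI = 2, AK = 1), a(Gv, "range", 28, 32), a(Pv, "range", 11, 15)),
    row(n(AI = 1), a(Gv, "eq", 34), a(Pv, "eq", 6.4)),
    row(n(AK = 2), a(Gv, "eq", 36), a(Pv, "range", 25, 34), a("Atopobium", "range", 17, 23)),
    row(n(AI = 1, AK = 1, CG = 4), a(Gv, "range", 39, 45), a(Li, "range", 37, 38.5)),
    row(n(AK = 4, CG = 2), a(Gv, "range", 30, 42), a(Pv, "range", 4, 10),
        a("Atopobium", "range", 4, 10), a("Streptococcus", "range", 4, 10),
        a("Veillonella", "range", 4, 10), a("Anaerococcus", "range", 4, 10)),
    row(n(AK = 1, CG = 4), a(Gv, "range", 30, 42), a(Pv, "range", 4, 10),
        a(CLV, "range", 4, 10), a("Megasphaera", "range", 4, 10),
        a("Sneathia", "range", 4, 10), a(Li, "range", 4, 10)),

    # --- polymicrobial, Prevotella on top below 50% ---
    row(n(AI = 3), a(Pv, "eq", 18), a(Li, "range", 1, 4), a(Lc, "range", 0.5, 2)),
    row(n(AC = 2), a(Pv, "gt", 36, 45), a(Gv, "eq", 0)),
    row(n(AC = 1, AI = 2), a(Pv, "range", 16, 46)),
    row(n(AC = 2, CG = 6), a(Pv, "range", 30, 45), a(Gv, "range", 4, 12),
        a(CLV, "range", 3, 10), a("Megasphaera", "range", 3, 10),
        a("Sneathia", "range", 3, 10), a(Li, "range", 3, 10)),
    row(n(AC = 2, CG = 4), a(Pv, "range", 30, 45), a(Gv, "range", 4, 12),
        a("Gemella", "range", 3, 8), a("Megasphaera", "range", 3, 8),
        a("Sneathia", "range", 3, 8), a(Li, "range", 3, 8),
        a("Mycoplasma", "range", 1, 5)),

    # --- polymicrobial, other genera on top below 50% ---
    row(n(AI = 3), a(Li, "range", 25, 45)),
    row(n(AI = 1), a("Corynebacterium", "eq", 27)),
    row(n(CG = 1), a("Bifidobacterium", "eq", 47), a("Scardovia", "eq", 49)),
    row(n(AI = 2), a("Streptococcus", "eq", 46), a(Li, "eq", 13), a("Sneathia", "eq", 10)),
    row(n(AK = 1), a("Ureaplasma", "eq", 36), a("Escherichia-Shigella", "eq", 33),
        a("Staphylococcus", "eq", 16)),
    row(n(AK = 1), a("Clostridiales bacterium", "eq", 34), a(CLV, "eq", 16),
        a("Veillonella", "eq", 6.6)),
    row(n(AA = 1), a("Peptostreptococcus", "eq", 28), a(Pv, "eq", 25), a(Li, "eq", 13)),

    # --- G. vaginalis predominant (RA >= 50%) ---
    row(n(AC = 1, AK = 1), a(Gv, "eq", 53), a(Li, "eq", 47)),
    row(n(AC = 1, AK = 1), a(Gv, "gt", 60, 72), a("Sneathia", "range", 2, 7),
        a(CLV, "range", 2, 7), a("Megasphaera", "range", 2, 7),
        a("Atopobium", "range", 2, 7), a("Aerococcus", "range", 2, 7)),
    row(n(AI = 1), a(Gv, "eq", 54), a("Streptococcus", "eq", 45)),
    row(n(AI = 1), a(Gv, "eq", 68), a(Lg, "eq", 22)),

    # --- Prevotella predominant (RA >= 50%) ---
    row(n(AC = 1), a(Pv, "gt", 70)),

    # --- THPP predominant (RA >= 50%) ---
    row(n(AK = 1), a("Streptococcus", "eq", 60), a("Sneathia", "eq", 23), a(Gv, "eq", 9.0)),
    row(n(AK = 2), a("Streptococcus", "gt", 85)),
    row(n(AI = 1), a("Peptostreptococcus", "eq", 54)),
    row(n(AI = 1), a("Enterococcus", "gt", 80, 85), a("Bacilli", "eq", 15)),
    row(n(AI = 2), a("Staphylococcus", "range", 65, 86), a(Li, "range", 1, 4),
        a("Escherichia-Shigella", "range", 1, 4)),
    row(n(AI = 1, AK = 1), a("Escherichia-Shigella", "eq", 88), a(Li, "eq", 5),
        a("Anaerococcus", "range", 1, 5)),

    # --- other genera predominant (RA >= 50%) ---
    row(n(AI = 1), a("Finegoldia", "eq", 71)),
    row(n(AC = 1), a("Anaerococcus", "eq", 93), a("Howardella", "eq", 5)),
    row(n(AK = 1), a("Anaerococcus", "eq", 62), a(Gv, "eq", 26),
        a("Veillonella", "eq", 4.7), a(Pv, "eq", 2.0)),
    row(n(AC = 2), a(CLV, "ge", 80, 90), a(Gv, "range", 2, 6.2)),
    row(n(AK = 1), a("Ralstonia", "gt", 51, 60), a("Corynebacterium", "eq", 9.0),
        a("Streptococcus", "range", 1, 4)),
    row(n(CG = 1), a("Bifidobacterium", "gt", 98))
  )
}

#' @rdname reference_cohort_constraints
#' @param seed integer seed for the fixture draws.
#' @return \code{reference_cohort_fixtures()}: a list with \code{table}
#'   (relative-mode \code{abundance_table} of 151 unlabeled compositions),
#'   \code{metadata} (data frame \code{sample_id}, \code{group}) and
#'   \code{constraints} (the per-sample \code{fixture_constraint}, for
#'   validation).
#' @export
reference_cohort_fixtures <- function(seed = 1L) {
  rows <- reference_cohort_constraints()
  groups <- character(); constraints <- list()
  for (r in rows) {
    for (g in names(r$n)) {
      reps <- r$n[[g]]
      groups <- c(groups, rep(g, reps))
      constraints <- c(constraints, rep(list(r$constraint), reps))
    }
  }
  # stable per-cohort sample ids
  ord <- order(groups)
  groups <- groups[ord]
  constraints <- constraints[ord]
  ids <- stats::ave(groups, groups, FUN = seq_along)
  ids <- sprintf("%s_%03d", groups, as.integer(ids))
  comps <- fixtures_from_descriptions(constraints, seed = seed)
  list(table = compositions_to_table(comps, sample_ids = ids),
       metadata = data.frame(sample_id = ids, group = groups),
       constraints = stats::setNames(constraints, ids))
}

#' Reference per-cohort mean relative-abundance profiles
#'
#' Loads the published top-30-taxa mean relative abundances of the five
#' reference cohorts (shipped with the package as
#' \code{extdata/reference_group_mean_ra.tsv}, values in percent) and
#' returns them as fractional compositions, together with the overall
#' profile computed as the unweighted mean of the five cohort profiles.
#' Because the source table is truncated to its top taxa, profiles sum to
#' slightly less than 1.
#'
#' @param registry a \code{taxon_registry} used to canonicalize taxon rows.
#' @return A list with \code{groups} (named list of compositions) and
#'   \code{overall} (composition), as from \code{\link{group_mean_profile}}.
#' @export
reference_group_means <- function(registry = default_registry()) {
  path <- system.file("extdata", "reference_group_mean_ra.tsv",
                      package = "vagcst", mustWork = TRUE)
  tab <- read_abundance_table(path, registry, orientation = "taxa_as_rows",
                              mode = "percent")
  groups <- lapply(stats::setNames(sample_ids(tab), sample_ids(tab)),
                   function(g) tab$values[g, ])
  list(groups = groups, overall = Reduce(`+`, groups) / length(groups))
}
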