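#' Fixture constraints on a single composition
#'
#' A fixture constraint is a set of numeric assertions on taxon relative
#' abundances (in percent), realized by
#' \code{\link{fixtures_from_descriptions}}. Comparators: \code{"eq"} (exact
#' value), \code{"gt"}/\code{"ge"} (lower bound, optionally with an upper
#' bound in \code{hi}), \code{"lt"}/\code{"le"} (upper bound) and
#' \code{"range"} (inclusive \code{lo}-\code{hi}). Mass not claimed by the
#' assertions is distributed over a pool of heterogeneous low-abundance
#' taxa, each kept below 7 percent.
#'
#' @param ... assertions built with \code{\link{ra_assert}}.
#' @return A list of class \code{fixture_constraint}.
#' @export
fixture_constraint <- function(...) {
  assertions <- list(...)
  ok <- vapply(assertions, function(a) {
    is.list(a) && all(c("taxon", "cmp", "lo") %in% names(a))
  }, TRUE)
  if (length(assertions) == 0L || any(!ok)) {
    stop_vagcst("fixture_constraint takes one or more ra_assert() assertions")
  }
  taxa <- vapply(assertions, `[[`, "", "taxon")
  if (anyDuplicated(taxa)) {
    stop_vagcst("duplicate taxon in fixture constraint: ",
                paste(taxa[duplicated(taxa)], collapse = ", "))
  }
  structure(list(assertions = assertions), class = "fixture_constraint")
}

#' @rdname fixture_constraint
#' @param taxon canonical taxon name.
#' @param cmp comparator: \code{"eq"}, \code{"gt"}, \code{"ge"},
#'   \code{"lt"}, \code{"le"} or \code{"range"}.
#' @param lo bound (percent); for \code{"lt"}/\code{"le"} the upper bound.
#' @param hi optional upper bound (percent) for \code{"gt"}/\code{"ge"}/
#'   \code{"range"}.
#' @export
ra_assert <- function(taxon, cmp, lo, hi = NA_real_) {
  cmp <- match.arg(cmp, c("eq", "gt", "ge", "lt", "le", "range"))
  if (cmp == "range" && is.na(hi)) stop_vagcst("range assertion needs hi")
  list(taxon = taxon, cmp = cmp, lo = lo, hi = hi)
}

# the "heterogeneous bacteria" pool: low-abundance filler taxa, each < 7%
het_pool <- function() {
  c("Sneathia", "Megasphaera", "Atopobium", "Clostridiales bacterium",
    "Dialister", "Parvimonas", "Mycoplasma", "Ureaplasma", "Finegoldia",
    "Peptoniphilus", "Mobiluncus", "Corynebacterium", "Howardella",
    "Porphyromonas", "Acinetobacter", "Fusobacterium")
}

HET_CAP <- 7  # percent, exclusive upper bound per heterogeneous-tail taxon

# check a realized composition (fractions) against a constraint (percent)
satisfies_constraint <- function(composition, constraint, tol = 1e-9) {
  pct <- composition * 100
  for (a in constraint$assertions) {
    v <- if (a$taxon %in% names(pct)) unname(pct[a$taxon]) else 0
    ok <- switch(a$cmp,
                 eq = abs(v - a$lo) <= 1e-6,
                 gt = v > a$lo &&
                   (is.na(a$hi) || v <= a$hi + tol),
                 ge = v >= a$lo - tol &&
                   (is.na(a$hi) || v <= a$hi + tol),
                 lt = v < a$lo,
                 le = v <= a$lo + tol,
                 range = v >= a$lo - tol && v <= a$hi + tol)
    if (!ok) return(FALSE)
  }
  TRUE
}

# realize one composition (fractions, sums to 1) from a constraint; assumes
# the RNG state is already seeded by the caller
realize_constraint <- function(constraint) {
  as_ <- constraint$assertions
  is_eq <- vapply(as_, function(a) a$cmp == "eq", TRUE)
  lower <- vapply(as_, function(a) {
    switch(a$cmp, eq = a$lo, gt = a$lo, ge = a$lo, range = a$lo, 0)
  }, 0)
  if (sum(lower) > 100 + 1e-9) {
    stop_vagcst("unsatisfiable constraint: lower bounds sum to ",
                format(sum(lower)), "% (> 100%)")
  }
  taxa <- vapply(as_, `[[`, "", "taxon")
  values <- stats::setNames(rep(NA_real_, length(as_)), taxa)
  values[is_eq] <- vapply(as_[is_eq], `[[`, 0, "lo")

  # bounded assertions drawn sequentially, always reserving the later
  # assertions' lower bounds so the total can never exceed 100%
  idx <- which(!is_eq)
  for (j in seq_along(idx)) {
    i <- idx[j]
    a <- as_[[i]]
    reserved <- if (j < length(idx)) sum(lower[idx[(j + 1L):length(idx)]]) else 0
    budget <- 100 - sum(values, na.rm = TRUE) - reserved
    lo <- switch(a$cmp, gt = a$lo, ge = a$lo, range = a$lo, 0)
    hi <- switch(a$cmp,
                 gt = if (is.na(a$hi)) Inf else a$hi,
                 ge = if (is.na(a$hi)) Inf else a$hi,
                 range = a$hi,
                 lt = a$lo, le = a$lo)
    hi_eff <- min(hi, budget)
    if (hi_eff < lo - 1e-9 || (a$cmp == "gt" && hi_eff <= lo)) {
      stop_vagcst("unsatisfiable constraint: no headroom for '", a$taxon,
                  "' ", a$cmp, " ", a$lo)
    }
    u <- switch(a$cmp,
                gt = stats::runif(1, 0.05, 0.9),  # strictly above lo
                lt = stats::runif(1, 0.05, 0.9),  # strictly below hi
                stats::runif(1, 0, 0.9))
    values[i] <- if (a$cmp %in% c("lt", "le")) {
      u * hi_eff
    } else {
      lo + u * (hi_eff - lo)
    }
  }

  tail <- 100 - sum(values)
  if (tail < -1e-9) stop_vagcst("internal error: assertions exceed 100%")
  if (tail > 1e-9) {
    pool <- setdiff(het_pool(), taxa)
    if (tail > length(pool) * HET_CAP) {
      stop_vagcst("unsatisfiable constraint: ", format(tail),
                  "% of heterogeneous tail exceeds pool capacity")
    }
    w <- stats::rgamma(length(pool), shape = 1)
    v <- tail * w / sum(w)
    # enforce the < 7% per-taxon cap by redistributing excess mass
    cap <- HET_CAP - 1e-3
    for (it in 1:100) {
      over <- v > cap
      if (!any(over)) break
      excess <- sum(v[over] - cap)
      v[over] <- cap
      free <- !over & v < cap
      v[free] <- v[free] + excess * w[free] / sum(w[free])
    }
    names(v) <- pool
    values <- c(values, v[v > 0])
  }
  values / 100
}

#' Generate unlabeled fixture compositions from cluster descriptions
#'
#' Realizes one composition per constraint: exact assertions are honoured
#' verbatim, bounded assertions are drawn inside their bounds, and the
#' remaining mass is spread over a pool of heterogeneous low-abundance taxa
#' (each below 7 percent). Compositions sum to 1 and are deterministic per
#' seed. The fixtures deliberately carry no CST label: labels are meant to
#' be recovered by \code{\link{assign_cst}}.
#'
#' @param constraints list of \code{\link{fixture_constraint}} objects.
#' @param seed integer seed.
#' @return List of compositions (named numeric vectors summing to 1).
#' @examples
#' cst2_like <- fixture_constraint(
#'   ra_assert("Lactobacillus gasseri", "eq", 52),
#'   ra_assert("Lactobacillus iners", "eq", 43))
#' comp <- fixtures_from_descriptions(list(cst2_like), seed = 1)[[1]]
#' sum(comp)  # 1
#' @export
fixtures_from_descriptions <- function(constraints, seed = 1L) {
  with_seed(seed, lapply(constraints, realize_constraint))
}

#' Stack compositions into a relative abundance table
#'
#' @param compositions list of named numeric vectors summing to 1.
#' @param sample_ids character vector of ids (defaults to S1, S2, ...).
#' @return An \code{abundance_table} in relative mode over the union of taxa.
#' @export
compositions_to_table <- function(compositions,
                                  sample_ids = paste0("S", seq_along(compositions))) {
  taxa <- unique(unlist(lapply(compositions, names)))
  m <- matrix(0, nrow = length(compositions), ncol = length(taxa),
              dimnames = list(sample_ids, taxa))
  for (i in seq_along(compositions)) {
    m[i, names(compositions[[i]])] <- compositions[[i]]
  }
  abundance_table(m, "relative")
}

#' Built-in CST composition archetypes
#'
#' One archetype per extended CST (I, II, III, IV-A, IV-B, IV-C, VI, VII,
#' VIII, IX): a mean relative-abundance profile whose dominant taxon sits
#' mid-range of the published cluster descriptions, plus a Dirichlet
#' concentration (precision) parameter. At the default concentration of 50
#' the dominant taxon's standard deviation across simulated samples is about
#' 0.05.
#'
#' @param concentration Dirichlet precision applied to every archetype.
#' @return Named list of archetypes, each a list with \code{cst},
#'   \code{mean_profile} (composition summing to 1) and
#'   \code{concentration}.
#' @export
archetypes_from_table <- function(concentration = 50) {
  p <- list(
    "I" = c("Lactobacillus crispatus" = 0.85, "Lactobacillus iners" = 0.06,
            "Gardnerella vaginalis" = 0.02, "Prevotella" = 0.02,
            "Atopobium" = 0.02, "Sneathia" = 0.01, "Megasphaera" = 0.01,
            "Streptococcus" = 0.01),
    "II" = c("Lactobacillus gasseri" = 0.70, "Lactobacillus iners" = 0.15,
             "Lactobacillus crispatus" = 0.05, "Gardnerella vaginalis" = 0.03,
             "Atopobium" = 0.03, "Prevotella" = 0.02, "Streptococcus" = 0.02),
    "III" = c("Lactobacillus iners" = 0.80, "Lactobacillus crispatus" = 0.05,
              "Gardnerella vaginalis" = 0.05, "Prevotella" = 0.03,
              "Atopobium" = 0.03, "Megasphaera" = 0.02, "Sneathia" = 0.02),
    "IV-A" = c("Gardnerella vaginalis" = 0.35, "Atopobium" = 0.12,
               "Prevotella" = 0.10, "Lactobacillus iners" = 0.09,
               "Sneathia" = 0.07, "Megasphaera" = 0.07,
               "Candidatus Lachnocurva vaginae" = 0.06, "Veillonella" = 0.05,
               "Anaerococcus" = 0.04, "Dialister" = 0.03,
               "Streptococcus" = 0.02),
    "IV-B" = c("Prevotella" = 0.32, "Gardnerella vaginalis" = 0.11,
               "Sneathia" = 0.09, "Megasphaera" = 0.08,
               "Candidatus Lachnocurva vaginae" = 0.08,
               "Lactobacillus iners" = 0.08, "Atopobium" = 0.07,
               "Gemella" = 0.05, "Mycoplasma" = 0.04, "Anaerococcus" = 0.04,
               "Dialister" = 0.04),
    "IV-C" = c("Lactobacillus iners" = 0.35, "Streptococcus" = 0.12,
               "Corynebacterium" = 0.10, "Bifidobacterium" = 0.09,
               "Gardnerella vaginalis" = 0.06, "Prevotella" = 0.06,
               "Ureaplasma" = 0.05, "Peptostreptococcus" = 0.05,
               "Atopobium" = 0.04, "Sneathia" = 0.04, "Anaerococcus" = 0.04),
    "VI" = c("Gardnerella vaginalis" = 0.65, "Lactobacillus iners" = 0.10,
             "Atopobium" = 0.06, "Prevotella" = 0.05, "Sneathia" = 0.04,
             "Megasphaera" = 0.04, "Candidatus Lachnocurva vaginae" = 0.03,
             "Streptococcus" = 0.03),
    "VII" = c("Prevotella" = 0.72, "Gardnerella vaginalis" = 0.06,
              "Lactobacillus iners" = 0.05, "Sneathia" = 0.04,
              "Megasphaera" = 0.04, "Candidatus Lachnocurva vaginae" = 0.03,
              "Atopobium" = 0.03, "Dialister" = 0.03),
    "VIII" = c("Streptococcus" = 0.65, "Staphylococcus" = 0.08,
               "Enterococcus" = 0.06, "Escherichia-Shigella" = 0.05,
               "Lactobacillus iners" = 0.05, "Gardnerella vaginalis" = 0.03,
               "Sneathia" = 0.03, "Anaerococcus" = 0.03, "Atopobium" = 0.02),
    "IX" = c("Bifidobacterium" = 0.65, "Finegoldia" = 0.08,
             "Anaerococcus" = 0.08, "Gardnerella vaginalis" = 0.05,
             "Lactobacillus iners" = 0.04, "Corynebacterium" = 0.04,
             "Atopobium" = 0.03, "Veillonella" = 0.03))
  lapply(stats::setNames(names(p), names(p)), function(cst) {
    list(cst = cst, mean_profile = p[[cst]], concentration = concentration)
  })
}

#' Specify a synthetic multi-group cohort
#'
#' @param groups named list: group name -> list with \code{n} (samples) and
#'   \code{freq} (named CST frequency vector summing to 1).
#' @param depth_mean,depth_dispersion negative-binomial mean and dispersion
#'   (size) of per-sample read totals.
#' @param seed integer seed recorded in the spec.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(groups, depth_mean = 1e5, depth_dispersion = 10,
                        seed = 1L) {
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n) || gr$n < 1L) stop_vagcst("group '", g, "': n must be >= 1")
    if (abs(sum(gr$freq) - 1) > 1e-6) {
      stop_vagcst("group '", g, "': CST frequencies must sum to 1")
    }
    if (any(gr$freq < 0)) stop_vagcst("group '", g, "': negative frequency")
  }
  structure(list(groups = groups, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, seed = seed),
            class = "cohort_spec")
}

#' The default five-cohort specification
#'
#' Mirrors the study design the package emulates: five ethnic cohorts
#' (AA = 28, AC = 18, AI = 36, AK = 31, CG = 38 samples) with the
#' per-cohort CST frequencies observed in the published 151-sample tallies.
#'
#' @inheritParams cohort_spec
#' @return A \code{cohort_spec}.
#' @export
default_cohort_spec <- function(depth_mean = 1e5, depth_dispersion = 10,
                                seed = 1L) {
  f <- function(...) {
    counts <- c(...)
    list(n = sum(counts), freq = counts / sum(counts))
  }
  cohort_spec(list(
    AA = f("I" = 14, "III" = 13, "IV-C" = 1),
    AC = f("I" = 2, "III" = 3, "IV-B" = 7, "VI" = 2, "VII" = 1, "IX" = 3),
    AI = f("I" = 7, "II" = 1, "III" = 5, "IV-A" = 4, "IV-B" = 5, "IV-C" = 6,
           "VI" = 2, "VIII" = 5, "IX" = 1),
    AK = f("I" = 3, "III" = 8, "IV-A" = 10, "IV-C" = 2, "VI" = 2,
           "VIII" = 4, "IX" = 2),
    CG = f("I" = 7, "III" = 9, "IV-A" = 10, "IV-B" = 10, "IV-C" = 1,
           "IX" = 1)),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion, seed = seed)
}

#' Simulate a cohort of count samples from CST archetypes
#'
#' Per sample: a CST is drawn from its group's frequency vector, a
#' composition from \code{Dirichlet(concentration x mean_profile)}, a read
#' depth from a negative binomial, and counts from a multinomial at that
#' depth. Identical spec and seed give bit-identical output; the true CST of
#' every sample is returned alongside the table.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param archetypes archetype list from \code{\link{archetypes_from_table}}.
#' @return A list with \code{table} (counts-mode \code{abundance_table}),
#'   \code{truth} (data frame \code{sample_id}, \code{true_cst}) and
#'   \code{metadata} (data frame \code{sample_id}, \code{group}).
#' @export
simulate_cohort <- function(spec, archetypes = archetypes_from_table()) {
  used <- unique(unlist(lapply(spec$groups, function(g) names(g$freq))))
  missing <- setdiff(used, names(archetypes))
  if (length(missing)) {
    stop_vagcst("no archetype for CST(s): ", paste(missing, collapse = ", "))
  }
  taxa <- unique(unlist(lapply(archetypes, function(a) names(a$mean_profile))))
  alphas <- lapply(archetypes, function(a) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(a$mean_profile)] <- a$concentration * a$mean_profile
    v
  })
  with_seed(spec$seed, {
    rows <- list(); ids <- character(); grps <- character(); csts <- character()
    for (g in names(spec$groups)) {
      gr <- spec$groups[[g]]
      drawn <- sample(names(gr$freq), gr$n, replace = TRUE, prob = gr$freq)
      for (j in seq_len(gr$n)) {
        alpha <- alphas[[drawn[j]]]
        gam <- stats::rgamma(length(alpha), shape = alpha)
        comp <- gam / sum(gam)
        depth <- max(1L, stats::rnbinom(1L, mu = spec$depth_mean,
                                        size = spec$depth_dispersion))
        rows[[length(rows) + 1L]] <-
          as.integer(stats::rmultinom(1L, size = depth, prob = comp))
        ids <- c(ids, sprintf("%s_%03d", g, j))
        grps <- c(grps, g)
        csts <- c(csts, drawn[j])
      }
    }
    m <- do.call(rbind, rows)
    dimnames(m) <- list(ids, taxa)
    list(table = abundance_table(m, "counts"),
         truth = data.frame(sample_id = ids, true_cst = csts),
         metadata = data.frame(sample_id = ids, group = grps))
  })
}
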