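reg <- default_registry()

test_that("published cluster examples receive their expected CSTs", {
  cases <- list(
    list(c("Lactobacillus gasseri" = 0.52, "Lactobacillus iners" = 0.43,
           "Atopobium" = 0.05), "II"),
    list(c("Gardnerella vaginalis" = 0.54, "Streptococcus agalactiae" = 0.45,
           "Dialister" = 0.01), "VI"),
    list(c("Escherichia-Shigella" = 0.88, "Lactobacillus iners" = 0.05,
           "Anaerococcus" = 0.07), "VIII"),
    list(c("Bifidobacterium breve" = 0.98, "Atopobium" = 0.02), "IX"),
    list(c("Gardnerella vaginalis" = 0.44, "Atopobium" = 0.32,
           "Veillonella montpellierensis" = 0.11, "Dialister" = 0.13), "IV-A"),
    list(c("Prevotella" = 0.36, "Sneathia" = 0.25, "Megasphaera" = 0.2,
           "Atopobium" = 0.19), "IV-B"),
    list(c("Lactobacillus iners" = 0.45, "Sneathia" = 0.25,
           "Megasphaera" = 0.2, "Atopobium" = 0.1), "IV-C"),
    list(c("Prevotella" = 0.70, "Sneathia" = 0.1, "Megasphaera" = 0.1,
           "Atopobium" = 0.1), "VII"),
    list(c("Lactobacillus crispatus" = 0.99, "Prevotella" = 0.01), "I"),
    list(c("Lactobacillus iners" = 0.98, "Prevotella" = 0.02), "III"),
    list(c("Lactobacillus jensenii" = 0.55, "Atopobium" = 0.45), "V"))
  for (case in cases) {
    res <- assign_cst(case[[1]], reg)
    expect_identical(res$cst, case[[2]])
    expect_equal(res$dominant_ra, max(case[[1]]))
  }
})

test_that("the dominance threshold is inclusive at exactly 0.50", {
  x <- c("Lactobacillus crispatus" = 0.5, "Prevotella" = 0.3, "Sneathia" = 0.2)
  res <- assign_cst(x, reg)
  expect_identical(res$cst, "I")  # dominance branch, not IV-C
  expect_match(res$rationale, "dominance")
  # just below the threshold the polymicrobial branch fires
  y <- c("Lactobacillus crispatus" = 0.4999999, "Prevotella" = 0.3,
         "Sneathia" = 0.2000001)
  expect_identical(assign_cst(y, reg)$cst, "IV-C")
})

test_that("exact ties break by group priority and are recorded", {
  x <- c("Gardnerella vaginalis" = 0.5, "Lactobacillus iners" = 0.5)
  res <- assign_cst(x, reg)
  expect_identical(res$cst, "III")  # LACTOBACILLUS outranks GARDNERELLA
  expect_match(res$rationale, "tie")
  # alphabetical within a group
  y <- c("Megasphaera" = 0.5, "Atopobium" = 0.5)
  expect_identical(assign_cst(y, reg)$dominant_taxon, "Atopobium")
})

test_that("a dominant non-canonical Lactobacillus is UNRESOLVED unless folded", {
  x <- c("Lactobacillus salivarius" = 0.6, "Lactobacillus iners" = 0.4)
  expect_identical(assign_cst(x, reg)$cst, "UNRESOLVED")
  cfg <- classifier_config(fold_unresolved_into = "IX")
  expect_identical(assign_cst(x, reg, cfg)$cst, "IX")
  # sub-threshold non-canonical Lactobacillus top falls to IV-C
  y <- c("Lactobacillus salivarius" = 0.45, "Atopobium" = 0.3, "Dialister" = 0.25)
  expect_identical(assign_cst(y, reg)$cst, "IV-C")
})

test_that("malformed compositions are rejected", {
  expect_error(assign_cst(numeric(0), reg), "empty")
  expect_error(assign_cst(c("Prevotella" = 0.7), reg), "not normalized")
  expect_error(assign_cst(c("Prevotella" = 1.2, "Sneathia" = -0.2), reg),
               "negative")
  expect_error(classifier_config(dominance_threshold = 0), "in \\(0, 1\\]")
})

test_that("assign_cst agrees with the brute-force rule evaluator", {
  comps <- random_compositions(2000, seed = 11)
  got <- vapply(comps, function(x) assign_cst(x, reg)$cst, "")
  want <- vapply(comps, brute_force_cst, "")
  expect_identical(got, want)
})

test_that("raising the dominant taxon never changes an established label", {
  comps <- random_compositions(300, seed = 13)
  boost <- function(x, top, target) {
    y <- x * (1 - target) / (1 - x[[top]])
    y[top] <- target
    y
  }
  for (x in comps) {
    top <- names(x)[which.max(x)]
    targets <- c(max(max(x), 0.52), 0.7, 0.9, 0.999)
    labels <- vapply(targets, function(t) assign_cst(boost(x, top, t), reg)$cst, "")
    expect_identical(unique(labels), labels[1])
  }
})

test_that("cohort classification conserves samples and summaries tally", {
  fx <- reference_cohort_fixtures(seed = 2)
  asg <- classify_cohort(fx$table, fx$metadata)
  expect_identical(nrow(asg), 151L)
  expect_setequal(asg$sample_id, fx$metadata$sample_id)
  sm <- summarize_cst_counts(asg)
  # counts conserve N overall and per group
  expect_equal(unname(sm$n["overall"]), 151)
  expect_equal(sum(sm$counts[, "overall"]), 151)
  expect_equal(unname(colSums(sm$counts[, c("AA", "AC", "AI", "AK", "CG")])),
               c(28, 18, 36, 31, 38))
  # percentages per group sum to 100
  expect_true(all(abs(colSums(sm$percentages) - 100) < 0.1))
  # empty table gives an empty result
  empty <- abundance_table(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("a", "b"))),
                           "relative")
  expect_identical(nrow(classify_cohort(empty)), 0L)
  # one sample lands at 100% in its CST
  one <- compositions_to_table(list(c("Lactobacillus iners" = 1)), "s1")
  sm1 <- summarize_cst_counts(classify_cohort(one))
  expect_equal(unname(sm1$percentages["III", "overall"]), 100)
})
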