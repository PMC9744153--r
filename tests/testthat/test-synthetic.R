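test_that("exact assertions are honoured with a capped heterogeneous tail", {
  con <- fixture_constraint(
    ra_assert("Lactobacillus gasseri", "eq", 52),
    ra_assert("Lactobacillus iners", "eq", 43))
  comp <- fixtures_from_descriptions(list(con), seed = 1)[[1]]
  expect_equal(unname(comp["Lactobacillus gasseri"]), 0.52)
  expect_equal(unname(comp["Lactobacillus iners"]), 0.43)
  expect_equal(sum(comp), 1)
  tail <- comp[setdiff(names(comp), c("Lactobacillus gasseri",
                                      "Lactobacillus iners"))]
  expect_equal(sum(tail), 0.05)
  expect_true(all(tail < 0.07))
})

test_that("unsatisfiable constraints are rejected with the violated bound", {
  con <- fixture_constraint(ra_assert("Prevotella", "ge", 70),
                            ra_assert("Gardnerella vaginalis", "ge", 50))
  expect_error(fixtures_from_descriptions(list(con), seed = 1),
               "lower bounds sum to 120")
  # when every pool taxon is pinned low the remaining tail has nowhere to go
  pins <- lapply(vagcst:::het_pool(), ra_assert, cmp = "eq", lo = 0.1)
  con2 <- do.call(fixture_constraint,
                  c(list(ra_assert("Prevotella", "eq", 0.5)), pins))
  expect_error(fixtures_from_descriptions(list(con2), seed = 1),
               "pool capacity")
})

test_that("the 151 reference fixtures satisfy their own constraints", {
  fx <- reference_cohort_fixtures(seed = 3)
  expect_identical(nrow(fx$table$values), 151L)
  expect_true(all(abs(rowSums(fx$table$values) - 1) < 1e-9))
  ok <- vapply(names(fx$constraints), function(id) {
    vagcst:::satisfies_constraint(fx$table$values[id, ], fx$constraints[[id]])
  }, TRUE)
  expect_true(all(ok))
  # cohort sizes mirror the study design
  expect_equal(unname(table(fx$metadata$group)[c("AA", "AC", "AI", "AK", "CG")]),
               c(28, 18, 36, 31, 38), ignore_attr = TRUE)
  # deterministic per seed
  fx2 <- reference_cohort_fixtures(seed = 3)
  expect_identical(fx$table$values, fx2$table$values)
})

test_that("archetypes are normalized and classify as themselves", {
  arch <- archetypes_from_table()
  expect_setequal(names(arch), c("I", "II", "III", "IV-A", "IV-B", "IV-C",
                                 "VI", "VII", "VIII", "IX"))
  reg <- default_registry()
  for (a in arch) {
    expect_equal(sum(a$mean_profile), 1)
    expect_identical(assign_cst(a$mean_profile, reg)$cst, a$cst)
  }
  expect_gte(arch[["I"]]$mean_profile[["Lactobacillus crispatus"]], 0.55)
})

test_that("cohort simulation keeps its books and honours degenerate mixes", {
  spec <- cohort_spec(stats::setNames(rep(list(list(n = 30, freq = c("I" = 1))), 5),
                                      paste0("g", 1:5)),
                      depth_mean = 1e4, seed = 17)
  sim <- simulate_cohort(spec)
  expect_identical(nrow(sim$table$values), 150L)
  expect_identical(nrow(sim$metadata), 150L)
  expect_identical(sim$table$mode, "counts")
  expect_true(all(sim$truth$true_cst == "I"))
  # same spec + seed: bit-identical output
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$table$values, sim2$table$values)
  expect_identical(sim$truth, sim2$truth)
  expect_error(cohort_spec(list(g = list(n = 2, freq = c("I" = 0.5)))),
               "sum to 1")
})

test_that("high concentration collapses samples onto archetype means", {
  spec <- cohort_spec(list(g = list(n = 50,
                                    freq = c("I" = 0.25, "III" = 0.25,
                                             "IV-B" = 0.25, "VIII" = 0.25))),
                      depth_mean = 2e4, seed = 19)
  sim <- simulate_cohort(spec, archetypes_from_table(concentration = 5000))
  asg <- classify_cohort(to_relative_abundance(sim$table))
  expect_identical(asg$cst, sim$truth$true_cst)  # 100% recovery
})

test_that("simulated group means converge on the mixture-implied mean", {
  # one group, an even I/IV-B mixture: implied Lactobacillus-total mean is
  # the average of the two archetypes' Lactobacillus totals
  arch <- archetypes_from_table()
  lac <- function(p) sum(p[grep("^Lactobacillus", names(p))])
  implied <- (lac(arch[["I"]]$mean_profile) + lac(arch[["IV-B"]]$mean_profile)) / 2
  spec <- cohort_spec(list(g = list(n = 600, freq = c("I" = 0.5, "IV-B" = 0.5))),
                      depth_mean = 2e4, seed = 23)
  sim <- simulate_cohort(spec, arch)
  rel <- to_relative_abundance(sim$table)
  v <- group_variable(rel, "LACTOBACILLUS")
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - implied), 3 * se)
})
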