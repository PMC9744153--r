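test_that("abundance tables round-trip through write/read", {
  tab <- toy_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, f)
  back <- read_abundance_table(f)
  expect_identical(back$mode, "counts")
  expect_equal(back$values, tab$values)
})

test_that("synonym columns merge by summation on read", {
  # both the old and the new name of the renamed taxon appear as columns
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tShuttleworthia\tCandidatus Lachnocurva vaginae\tLactobacillus iners",
               "s1\t100\t50\t850",
               "s2\t0\t200\t800",
               "s3\t70\t30\t900"), f)
  tab <- read_abundance_table(f)
  expect_identical(tab$mode, "counts")
  expect_true("Candidatus Lachnocurva vaginae" %in% colnames(tab$values))
  expect_false("Shuttleworthia" %in% colnames(tab$values))
  # oracle: manual column addition
  expect_equal(unname(tab$values[, "Candidatus Lachnocurva vaginae"]),
               c(150, 200, 100))
})

test_that("percentage tables are detected and rescaled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tLactobacillus iners\tPrevotella",
               "s1\t60\t40",
               "s2\t25\t75"), f)
  tab <- read_abundance_table(f)
  expect_identical(tab$mode, "relative")
  expect_equal(rowSums(tab$values), c(s1 = 1, s2 = 1))
  expect_error(read_abundance_table({
    g <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tA\tB", "s1\t-1\t2"), g)
    g
  }), "negative")
})

test_that("count normalization behaves and preserves rank order", {
  tab <- toy_counts()
  rel <- to_relative_abundance(tab)
  expect_identical(rel$mode, "relative")
  expect_equal(unname(rel$values["s1", ]), c(0.8, 0.15, 0.05))
  # degenerate single-taxon sample
  one <- abundance_table(matrix(7L, 1, 1, dimnames = list("s", "Prevotella")),
                         "counts")
  expect_equal(unname(to_relative_abundance(one)$values[1, 1]), 1)
  # property: every row sums to 1 and within-sample rank order is preserved
  set.seed(1)
  m <- matrix(rpois(50, 40) + 1, nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:10)))
  r <- to_relative_abundance(abundance_table(m, "counts"))
  expect_true(all(abs(rowSums(r$values) - 1) < 1e-9))
  for (i in 1:5) expect_identical(order(r$values[i, ]), order(m[i, ]))
  # zero-total sample errors with its name
  m2 <- m; m2["s3", ] <- 0
  expect_error(to_relative_abundance(abundance_table(m2, "counts")), "s3")
})

test_that("rarefaction subsamples to exact depth and drops shallow samples", {
  m <- matrix(c(70000L, 30000L,   # 100k reads
                200L, 0L,         # below depth
                50L, 150L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("deep", "shallow1", "shallow2"),
                              c("Lactobacillus iners", "Prevotella")))
  tab <- abundance_table(m, "counts")
  expect_warning(rar <- rarefy_counts(tab, depth = 80000, seed = 1),
                 "below depth")
  expect_identical(rownames(rar$values), "deep")
  expect_equal(unname(rowSums(rar$values)), 80000)
  # forced outcome: single-taxon sample
  one <- abundance_table(matrix(200L, 1, 1, dimnames = list("s", "Prevotella")),
                         "counts")
  expect_equal(unname(rarefy_counts(one, depth = 50, seed = 1)$values[1, 1]), 50)
  # same seed is reproducible
  r1 <- suppressWarnings(rarefy_counts(tab, depth = 1000, seed = 5))
  r2 <- suppressWarnings(rarefy_counts(tab, depth = 1000, seed = 5))
  expect_identical(r1$values, r2$values)
  expect_error(rarefy_counts(abundance_table(
    matrix(10L, 1, 1, dimnames = list("s", "t")), "counts"), depth = 100),
    "below the rarefaction depth")
})

test_that("rarefaction is unbiased for taxon proportions", {
  # taxon at p = 0.3 in a 10,000-read sample, depth 1,000, 200 seeds
  m <- matrix(c(3000L, 7000L), 1, 2,
              dimnames = list("s", c("a", "b")))
  tab <- abundance_table(m, "counts")
  props <- vapply(1:200, function(s) {
    rarefy_counts(tab, depth = 1000, seed = s)$values[1, "a"] / 1000
  }, 0)
  se <- sqrt(0.3 * 0.7 / 1000 * (1 - 999 / 9999)) / sqrt(length(props))
  expect_lt(abs(mean(props) - 0.3), 3 * se)
})

test_that("group mean profiles use the unweighted-mean overall convention", {
  set.seed(3)
  m <- matrix(rgamma(300, 1), nrow = 30)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", 1:30), paste0("t", 1:10))
  tab <- abundance_table(m, "relative")
  meta <- data.frame(sample_id = rownames(m),
                     group = rep(c("g1", "g2", "g3"), each = 10))
  prof <- group_mean_profile(tab, meta)
  # direct arithmetic oracle
  for (g in c("g1", "g2", "g3")) {
    rows <- meta$sample_id[meta$group == g]
    expect_equal(prof$groups[[g]], colMeans(m[rows, ]))
  }
  expect_equal(prof$overall,
               (prof$groups$g1 + prof$groups$g2 + prof$groups$g3) / 3)
  # pooled convention differs when group sizes are unbalanced
  meta2 <- meta; meta2$group <- c(rep("g1", 5), rep("g2", 25))
  p_gm <- group_mean_profile(tab, meta2)$overall
  p_pool <- group_mean_profile(tab, meta2, overall = "pooled")$overall
  expect_equal(p_pool, colMeans(m))
  expect_false(isTRUE(all.equal(p_gm, p_pool)))
  # permutation invariance to sample order
  perm <- sample(30)
  tab2 <- abundance_table(m[perm, ], "relative")
  prof2 <- group_mean_profile(tab2, meta)
  expect_equal(prof2$overall, prof$overall)
  # group of one sample equals that sample
  meta3 <- meta; meta3$group[1] <- "solo"
  expect_equal(group_mean_profile(tab, meta3)$groups$solo, m["s1", ])
})

test_that("panel totals sum member abundances", {
  prof <- c("Lactobacillus iners" = 0.5, "Prevotella" = 0.3, "Sneathia" = 0.2)
  expect_equal(panel_total(prof, character(0)), 0)
  expect_equal(panel_total(prof, names(prof)), 1)
  expect_equal(panel_total(prof, c("Prevotella", "Absent taxon")), 0.3)
  # canonicalization applies to the panel names
  reg <- default_registry()
  prof2 <- c("Escherichia-Shigella" = 0.1, "Lactobacillus iners" = 0.9)
  expect_equal(panel_total(prof2, "Escherichia", reg), 0.1)
})
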