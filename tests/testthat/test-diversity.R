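test_that("Shannon index matches closed-form values", {
  u4 <- stats::setNames(rep(0.25, 4), paste0("t", 1:4))
  expect_equal(shannon_index(u4), 2)                       # log2(4)
  expect_equal(shannon_index(c(t1 = 1)), 0)
  expect_equal(shannon_index(c(a = 0.5, b = 0.25, c = 0.25)), 1.5)
  # natural-log base
  expect_equal(shannon_index(u4, base = exp(1)), log(4))
  # zeros are ignored, not NaN
  expect_equal(shannon_index(c(a = 0.5, b = 0.5, c = 0)), 1)
})

test_that("the uniform composition maximizes Shannon diversity", {
  set.seed(8)
  k <- 6
  u <- stats::setNames(rep(1 / k, k), paste0("t", 1:k))
  h_max <- shannon_index(u)
  for (i in 1:50) {
    g <- rgamma(k, 1)
    p <- stats::setNames(g / sum(g), names(u))
    expect_lte(shannon_index(p), h_max + 1e-12)
  }
})

test_that("Bray-Curtis dissimilarities match the closed form", {
  m <- rbind(s1 = c(0.8, 0.2, 0), s2 = c(0.2, 0.2, 0.6),
             s3 = c(0.8, 0.2, 0), s4 = c(0, 0, 1))
  colnames(m) <- c("a", "b", "c")
  bc <- bray_curtis_matrix(abundance_table(m, "relative"))
  expect_equal(bc["s1", "s2"], 0.6)      # 1 - (0.2 + 0.2 + 0)
  expect_equal(bc["s1", "s3"], 0)        # identical samples
  expect_equal(bc["s1", "s4"], 1)        # disjoint supports
  expect_equal(bc, t(bc))                # symmetry
  expect_true(all(diag(bc) == 0))
  expect_true(all(bc >= 0 & bc <= 1))
})

test_that("Kruskal-Wallis battery handles ties, separation and errors", {
  meta <- data.frame(sample_id = paste0("s", 1:60),
                     group = rep(c("g1", "g2"), each = 30))
  # all values identical: statistic 0, p = 1
  same <- stats::setNames(rep(1.7, 60), meta$sample_id)
  res <- pairwise_group_test(same, meta)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  # strong separation: Normal(0,1) vs Normal(3,1)
  set.seed(30)
  v <- stats::setNames(c(rnorm(30, 0), rnorm(30, 3)), meta$sample_id)
  res <- pairwise_group_test(v, meta)
  expect_lt(res$adjusted_p[res$scope == "pair"], 0.01)
  expect_true(all(res$adjusted_p >= res$p_value))
  # three groups produce all three pairs with BH adjustment
  meta3 <- data.frame(sample_id = paste0("s", 1:30),
                      group = rep(c("a", "b", "c"), each = 10))
  set.seed(31)
  v3 <- stats::setNames(rnorm(30), meta3$sample_id)
  res3 <- pairwise_group_test(v3, meta3)
  expect_identical(sum(res3$scope == "pair"), 3L)
  expect_equal(res3$adjusted_p[res3$scope == "pair"],
               p.adjust(res3$p_value[res3$scope == "pair"], "BH"))
  # singleton group rejected
  meta_bad <- data.frame(sample_id = paste0("s", 1:3),
                         group = c("a", "a", "b"))
  expect_error(pairwise_group_test(stats::setNames(1:3, meta_bad$sample_id),
                                   meta_bad), "fewer than 2")
})

test_that("PERMANOVA attains its minimum p on separated groups", {
  spec <- cohort_spec(list(g1 = list(n = 12, freq = c("I" = 1)),
                           g2 = list(n = 12, freq = c("IV-B" = 1))),
                      depth_mean = 5e4, seed = 41)
  sim <- simulate_cohort(spec)
  rel <- to_relative_abundance(sim$table)
  d <- bray_curtis_matrix(rel)
  res <- permanova(d, sim$metadata, n_perm = 999, seed = 1)
  expect_equal(res$p_value, 0.001)  # (1 + 0) / (1 + 999)
  expect_gt(res$statistic, 1)
  # seeded: reproducible
  res2 <- permanova(d, sim$metadata, n_perm = 999, seed = 1)
  expect_identical(res, res2)
  # invariant to distance-preserving relabeling of the samples
  d2 <- d
  rownames(d2) <- colnames(d2) <- paste0("x_", rownames(d))
  meta2 <- data.frame(sample_id = paste0("x_", sim$metadata$sample_id),
                      group = sim$metadata$group)
  expect_equal(permanova(d2, meta2, n_perm = 199, seed = 7)$p_value,
               permanova(d, sim$metadata, n_perm = 199, seed = 7)$p_value)
  # singleton group and tiny permutation counts rejected
  bad <- sim$metadata; bad$group[1] <- "lonely"
  expect_error(permanova(d, bad, n_perm = 999), "singleton")
  expect_error(permanova(d, sim$metadata, n_perm = 10), ">= 99")
})

test_that("five archetype-distinct cohorts separate at p = 0.001", {
  sim <- simulate_cohort(default_cohort_spec(depth_mean = 2e4, seed = 20))
  rel <- to_relative_abundance(sim$table)
  res <- permanova(bray_curtis_matrix(rel), sim$metadata,
                   n_perm = 999, seed = 2)
  expect_equal(res$p_value, 0.001)
})
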