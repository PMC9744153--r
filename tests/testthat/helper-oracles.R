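# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive expected behaviour from first principles and
# never call the implementation paths they are used to check.

# 12 taxa spanning all five functional groups, with an independent
# hand-written group map (not taken from default_registry())
oracle_taxa <- c("Lactobacillus crispatus", "Lactobacillus gasseri",
                 "Lactobacillus iners", "Lactobacillus jensenii",
                 "Lactobacillus salivarius", "Gardnerella vaginalis",
                 "Prevotella", "Prevotella 6", "Streptococcus",
                 "Escherichia-Shigella", "Atopobium", "Bifidobacterium")

oracle_group <- c("Lactobacillus crispatus" = "LACTOBACILLUS",
                  "Lactobacillus gasseri" = "LACTOBACILLUS",
                  "Lactobacillus iners" = "LACTOBACILLUS",
                  "Lactobacillus jensenii" = "LACTOBACILLUS",
                  "Lactobacillus salivarius" = "LACTOBACILLUS",
                  "Gardnerella vaginalis" = "GARDNERELLA",
                  "Prevotella" = "PREVOTELLA",
                  "Prevotella 6" = "PREVOTELLA",
                  "Streptococcus" = "THPP",
                  "Escherichia-Shigella" = "THPP",
                  "Atopobium" = "OTHER",
                  "Bifidobacterium" = "OTHER")

# brute-force rule evaluator: checks every clause of the dominance rule
# table exhaustively and asserts exactly one fires
brute_force_cst <- function(x, thr = 0.5) {
  top <- names(x)[which.max(x)]
  r <- max(x)
  grp <- oracle_group[[top]]
  four <- c("I" = "Lactobacillus crispatus", "II" = "Lactobacillus gasseri",
            "III" = "Lactobacillus iners", "V" = "Lactobacillus jensenii")
  fired <- character()
  if (r >= thr && top %in% four) {
    fired <- c(fired, names(four)[four == top])
  }
  if (r >= thr && grp == "LACTOBACILLUS" && !top %in% four) {
    fired <- c(fired, "UNRESOLVED")
  }
  if (r >= thr && top == "Gardnerella vaginalis") fired <- c(fired, "VI")
  if (r >= thr && grp == "PREVOTELLA") fired <- c(fired, "VII")
  if (r >= thr && grp == "THPP") fired <- c(fired, "VIII")
  if (r >= thr && grp == "OTHER") fired <- c(fired, "IX")
  if (r < thr && top == "Gardnerella vaginalis") fired <- c(fired, "IV-A")
  if (r < thr && grp == "PREVOTELLA") fired <- c(fired, "IV-B")
  if (r < thr && !top == "Gardnerella vaginalis" && grp != "PREVOTELLA") {
    fired <- c(fired, "IV-C")
  }
  stopifnot(length(fired) == 1L)
  fired
}

# random compositions over the 12 oracle taxa; ties have probability zero
random_compositions <- function(n, seed, alpha = 0.7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    g <- rgamma(length(oracle_taxa), shape = alpha)
    stats::setNames(g / sum(g), oracle_taxa)
  })
}

# naive O(n^3) complete-linkage agglomeration over a distance matrix;
# returns merge heights and the k-cluster partition
naive_complete_linkage <- function(d, k) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1L]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1L])
    if (length(clusters) == k) {
      part <- integer(nrow(d))
      for (c_i in seq_along(clusters)) part[clusters[[c_i]]] <- c_i
      attr(heights, paste0("partition_k", k)) <- part
    }
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- clusters[-c(best[2L], best[3L])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# partition equality up to label permutation
same_partition <- function(a, b) {
  identical(unname(as.integer(factor(a, levels = unique(a)))),
            unname(as.integer(factor(b, levels = unique(b)))))
}

# small counts table used by abundance tests
toy_counts <- function() {
  m <- matrix(c(160L, 30L, 10L,
                20L, 140L, 40L,
                60L, 60L, 80L),
              nrow = 3L, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("Lactobacillus iners",
                                "Gardnerella vaginalis", "Prevotella")))
  abundance_table(m, "counts")
}
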