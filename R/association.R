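#' Choose Pearson or Spearman correlation via Shapiro-Wilk gating
#'
#' Applies the Shapiro-Wilk normality test to each variable; Pearson's
#' product-moment correlation is chosen only when both variables pass at the
#' given alpha (no evidence of non-normality), otherwise Spearman's rank
#' correlation.
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite,
#'   non-constant.
#' @param alpha significance level for the normality gate (default 0.05).
#' @return A list with \code{method} (\code{"pearson"} or
#'   \code{"spearman"}) and \code{normality}, a data frame with the W
#'   statistic and p-value per variable.
#' @export
choose_correlation_method <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop_vagcst("x and y lengths differ")
  if (length(x) < 4L) stop_vagcst("need n >= 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_vagcst("non-finite values in correlation input")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_vagcst("constant variable: normality and correlation are undefined")
  }
  sw <- function(v) {
    t <- stats::shapiro.test(v)
    c(W = unname(t$statistic), p_value = t$p.value)
  }
  rep_x <- sw(x)
  rep_y <- sw(y)
  normality <- data.frame(variable = c("x", "y"),
                          W = c(rep_x["W"], rep_y["W"]),
                          p_value = c(rep_x["p_value"], rep_y["p_value"]))
  method <- if (all(normality$p_value >= alpha)) "pearson" else "spearman"
  list(method = method, normality = normality)
}

# correlation of two numeric vectors with CI: Fisher z for Pearson,
# seeded bootstrap for Spearman
correlate_xy <- function(x, y, method = NULL, alpha = 0.05,
                         n_boot = 2000, seed = 1L) {
  if (is.null(method)) {
    method <- choose_correlation_method(x, y, alpha)$method
  }
  n <- length(x)
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
    ci <- as.numeric(ct$conf.int)
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    r <- unname(ct$estimate)
    p <- ct$p.value
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) == 0 || stats::var(y[i]) == 0) return(NA_real_)
      stats::cor(x[i], y[i], method = "spearman")
    }, 0))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  list(method = method, r = r, p_value = p, ci_low = ci[1L], ci_high = ci[2L],
       n = n)
}

# strength bands on |r|: strong >= 0.50, moderate 0.30-0.49, weak otherwise
correlation_band <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.50, "strong", ifelse(a >= 0.30, "moderate", "weak"))
}

#' Aggregated per-sample variables for correlation analysis
#'
#' Builds the per-sample value of a named variable from a relative-abundance
#' table: either the total relative abundance of a functional group
#' (\code{"LACTOBACILLUS"}, \code{"GARDNERELLA"}, \code{"PREVOTELLA"},
#' \code{"THPP"}, or the combined \code{"GARDNERELLA+PREVOTELLA"}) or a
#' single taxon's relative abundance (any other name, canonicalized).
#'
#' @param table an \code{abundance_table} in relative mode.
#' @param name variable name (group name or taxon label).
#' @param registry a \code{taxon_registry}.
#' @return Named numeric vector in \[0, 1\], one value per sample.
#' @export
group_variable <- function(table, name, registry = default_registry()) {
  if (table$mode != "relative") {
    stop_vagcst("group_variable expects a relative-mode table")
  }
  groups <- c("LACTOBACILLUS", "GARDNERELLA", "PREVOTELLA", "THPP", "OTHER")
  members <- if (name %in% groups) {
    group_members(name, registry)
  } else if (identical(name, "GARDNERELLA+PREVOTELLA")) {
    c(group_members("GARDNERELLA", registry),
      group_members("PREVOTELLA", registry))
  } else {
    canonical_names(name, registry, warn = FALSE)
  }
  sel <- colnames(table$values) %in% members
  stats::setNames(rowSums(table$values[, sel, drop = FALSE]),
                  sample_ids(table))
}

#' Correlation battery over pairs of aggregated variables
#'
#' For each pair, the method is chosen by
#' \code{\link{choose_correlation_method}} (overridable), the coefficient
#' and two-sided p-value come from \code{cor.test}, and a 95\% confidence
#' interval is attached: Fisher-z for Pearson, a seeded bootstrap (2,000
#' resamples by default) for Spearman. Each result is labelled
#' strong (|r| >= 0.50), moderate (0.30-0.49) or weak.
#'
#' @param table an \code{abundance_table} in relative mode.
#' @param pairs list of length-2 character vectors of variable names (see
#'   \code{\link{group_variable}}).
#' @param registry a \code{taxon_registry}.
#' @param alpha normality-gate significance level (default 0.05).
#' @param method \code{NULL} for the Shapiro-Wilk-gated choice, or force
#'   \code{"pearson"} / \code{"spearman"}.
#' @param n_boot bootstrap resamples for Spearman CIs.
#' @param seed integer seed for the bootstrap.
#' @return Data frame with columns \code{var_x}, \code{var_y},
#'   \code{method}, \code{n}, \code{r}, \code{p_value}, \code{ci_low},
#'   \code{ci_high}, \code{band}.
#' @export
correlate_groups <- function(table, pairs, registry = default_registry(),
                             alpha = 0.05, method = NULL, n_boot = 2000,
                             seed = 1L) {
  if (!is.null(method)) method <- match.arg(method, c("pearson", "spearman"))
  rows <- lapply(pairs, function(p) {
    x <- group_variable(table, p[[1L]], registry)
    y <- group_variable(table, p[[2L]], registry)
    res <- correlate_xy(x, y, method = method, alpha = alpha,
                        n_boot = n_boot, seed = seed)
    data.frame(var_x = p[[1L]], var_y = p[[2L]], method = res$method,
               n = res$n, r = res$r, p_value = res$p_value,
               ci_low = res$ci_low, ci_high = res$ci_high,
               band = correlation_band(res$r))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The default correlation battery
#'
#' The pairs examined in the THPP co-occurrence analysis: THPP against
#' Lactobacillus and against the combined obligate anaerobes, the
#' Lactobacillus / Gardnerella / Prevotella triangle, and M. hominis
#' against each of the three.
#'
#' @return List of variable-name pairs for \code{\link{correlate_groups}}.
#' @export
default_correlation_pairs <- function() {
  list(c("THPP", "LACTOBACILLUS"),
       c("THPP", "GARDNERELLA+PREVOTELLA"),
       c("LACTOBACILLUS", "GARDNERELLA"),
       c("LACTOBACILLUS", "PREVOTELLA"),
       c("GARDNERELLA", "PREVOTELLA"),
       c("Mycoplasma hominis", "GARDNERELLA"),
       c("Mycoplasma hominis", "PREVOTELLA"),
       c("Mycoplasma hominis", "LACTOBACILLUS"))
}
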