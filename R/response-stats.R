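#' Choose parametric vs nonparametric comparison path
#'
#' Applies the Shapiro-Wilk normality test to every group; the comparison is
#' `"parametric"` (ANOVA family) only if every group passes at p > 0.05,
#' otherwise `"nonparametric"` (rank-based family).
#'
#' @param groups Named list of numeric score vectors, one per treatment;
#'   every group needs n >= 3 (normality is untestable below that).
#' @return A list of class `test_path` with `method` and the per-group
#'   Shapiro-Wilk table.
#' @export
select_test_path <- function(groups) {
  check_groups(groups, min_n = 3L, min_groups = 2L)
  tab <- tibble::tibble(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    w = NA_real_,
    p = NA_real_
  )
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(unique(g)) == 1L) {
      # zero variance: shapiro.test is undefined; constants are not evidence
      # of normality, route to the rank-based path
      tab$w[i] <- NA_real_
      tab$p[i] <- 0
    } else {
      sw <- shapiro.test(g)
      tab$w[i] <- unname(sw$statistic)
      tab$p[i] <- sw$p.value
    }
  }
  method <- if (all(tab$p > 0.05)) "parametric" else "nonparametric"
  structure(list(method = method, shapiro = tab), class = "test_path")
}

check_groups <- function(groups, min_n = 3L, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups) {
    stop_validation(sprintf("need at least %d groups", min_groups))
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop_validation("groups must be a named list of score vectors")
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < min_n)) {
    stop_validation(sprintf(
      "group(s) with fewer than %d observations: %s",
      min_n, paste(names(groups)[n < min_n], collapse = ", ")
    ))
  }
  bad <- vapply(groups, function(g) !is.numeric(g) || anyNA(g) || any(!is.finite(g)),
                logical(1))
  if (any(bad)) {
    stop_validation(sprintf("non-finite scores in group(s): %s",
                            paste(names(groups)[bad], collapse = ", ")))
  }
  invisible(n)
}

#' Kruskal-Wallis omnibus test across treatments
#'
#' Rank-based H statistic with tie correction; p-value from the chi-square
#' approximation with k - 1 degrees of freedom. When every observation is
#' identical there is no rank variation and the result is H = 0, p = 1.
#'
#' @param groups Named list of numeric score vectors (>= 2 groups, total
#'   n >= 5).
#' @return A list with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_n = 1L, min_groups = 2L)
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 5L) stop_validation("Kruskal-Wallis needs total n >= 5")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                method = "Kruskal-Wallis rank sum test"))
  }
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = TRUE)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test for each pair in the comparison family. The exact
#' distribution (equivalent to exhaustive enumeration of group assignments)
#' is used when both groups have n <= 8 and the pooled data are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used, and the method chosen is reported per pair. Adjusted
#' p = min(1, raw p x family size). The family is given explicitly and is
#' never inferred from significance.
#'
#' @param groups Named list of numeric score vectors (each n >= 3).
#' @param family Data frame (or list of length-2 character vectors) of
#'   unordered treatment pairs forming the Bonferroni family. Default: all
#'   unordered pairs of `groups`.
#' @return A list of class `comparison_result` with the pairwise table
#'   (raw p, Bonferroni-adjusted p, significance tier at 0.05/0.01/0.001)
#'   and the family size.
#' @export
pairwise_wilcoxon_bonferroni <- function(groups, family = NULL) {
  check_groups(groups, min_n = 3L, min_groups = 2L)
  if (is.null(family)) {
    cmb <- utils::combn(names(groups), 2L)
    family <- tibble::tibble(a = cmb[1, ], b = cmb[2, ])
  } else if (is.list(family) && !is.data.frame(family)) {
    family <- tibble::tibble(
      a = vapply(family, `[`, character(1), 1L),
      b = vapply(family, `[`, character(1), 2L)
    )
  } else {
    family <- tibble::as_tibble(family)
    names(family)[1:2] <- c("a", "b")
  }
  if (nrow(family) == 0L) stop_validation("comparison family is empty")
  unknown <- setdiff(unique(c(family$a, family$b)), names(groups))
  if (length(unknown) > 0L) {
    stop_validation(sprintf("family names treatment(s) not in groups: %s",
                            paste(unknown, collapse = ", ")))
  }
  m <- nrow(family)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    x <- groups[[family$a[i]]]
    y <- groups[[family$b[i]]]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && length(x) <= 8L && length(y) <= 8L
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = !exact)
    )
    rows[[i]] <- tibble::tibble(
      a = family$a[i], b = family$b[i],
      n_a = length(x), n_b = length(y),
      statistic = unname(wt$statistic),
      method = if (exact) "exact" else "normal approximation",
      p = wt$p.value,
      p_adj = min(1, wt$p.value * m)
    )
  }
  pairwise <- dplyr::bind_rows(rows)
  pairwise$tier <- as.character(significance_tier(pairwise$p_adj))
  structure(list(pairwise = pairwise, family_size = m,
                 correction = "Bonferroni"),
            class = "comparison_result")
}

#' Full treatment comparison: omnibus test plus corrected pairwise tests
#'
#' Runs the Kruskal-Wallis omnibus test across all groups and the
#' Bonferroni-corrected pairwise Wilcoxon tests over the stated family —
#' the standard analysis for per-neuron maximum-response scores, which are
#' typically not normally distributed.
#'
#' @inheritParams pairwise_wilcoxon_bonferroni
#' @return A `comparison_result` with `omnibus`, `pairwise`, `family_size`.
#' @export
compare_treatments <- function(groups, family = NULL) {
  omnibus <- kruskal_wallis(groups)
  res <- pairwise_wilcoxon_bonferroni(groups, family = family)
  res$omnibus <- omnibus
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>")
  if (!is.null(x$omnibus)) {
    cat(sprintf(" Kruskal-Wallis H = %.4g, df = %d, p = %.4g",
                x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  }
  cat(sprintf("\n%d pairwise Wilcoxon tests, Bonferroni family size %d\n",
              nrow(x$pairwise), x$family_size))
  print(x$pairwise)
  invisible(x)
}

#' Bootstrap synergy excess for peptide co-application
#'
#' Quantifies whether the response to a co-applied pair exceeds the sum of
#' the single-peptide responses:
#' `excess = central(combined) - (central(A) + central(B))`, with the median
#' as the default central tendency (scores are analyzed nonparametrically; a
#' mean-based variant is available). Uncertainty comes from a percentile
#' bootstrap resampling each group independently; the p-value is one-sided
#' for excess > 0 (the directional claim of interest) and computed with the
#' add-one rule, so its minimum attainable value is `1 / (n_boot + 1)`.
#'
#' @param combined,single_a,single_b Numeric score vectors (each n >= 3).
#' @param n_boot Number of bootstrap resamples (>= 1000; fewer is refused as
#'   unstable).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param center `"median"` (default) or `"mean"`.
#' @param conf_level Confidence level of the percentile interval.
#' @return A list of class `synergy_result` with `excess`, `ci`, `p_value`,
#'   group sizes, `n_boot` and `seed`.
#' @export
synergy_excess <- function(combined, single_a, single_b, n_boot = 2000,
                           seed, center = c("median", "mean"),
                           conf_level = 0.95) {
  center <- match.arg(center)
  groups <- list(combined = combined, A = single_a, B = single_b)
  check_groups(groups, min_n = 3L, min_groups = 3L)
  if (missing(seed)) stop_validation("`seed` is required for the bootstrap")
  assert_number(n_boot, "n_boot", lower = 1)
  if (n_boot < 1000) stop_validation("n_boot < 1000 is refused as unstable")
  cf <- if (center == "median") median else mean
  excess <- cf(combined) - (cf(single_a) + cf(single_b))

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  boot <- numeric(n_boot)
  nC <- length(combined); nA <- length(single_a); nB <- length(single_b)
  for (b in seq_len(n_boot)) {
    boot[b] <- cf(combined[sample.int(nC, nC, replace = TRUE)]) -
      (cf(single_a[sample.int(nA, nA, replace = TRUE)]) +
         cf(single_b[sample.int(nB, nB, replace = TRUE)]))
  }
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  ci[1] <- min(ci[1], excess)
  ci[2] <- max(ci[2], excess)
  p_value <- (1 + sum(boot <= 0)) / (n_boot + 1)
  structure(
    list(excess = excess, ci = ci, p_value = p_value, center = center,
         n = c(combined = nC, A = nA, B = nB), n_boot = n_boot,
         seed = as.integer(seed), conf_level = conf_level),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "<synergy_result> excess = %.4g [%g%% CI %.4g, %.4g], one-sided p = %.4g (%s, %d bootstrap resamples, seed %d)\n",
    x$excess, 100 * x$conf_level, x$ci[1], x$ci[2], x$p_value, x$center,
    x$n_boot, x$seed
  ))
  invisible(x)
}
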