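#' Per-replicate dormancy proportions
#'
#' Computes, for each replicate vial, the proportion of dissected females
#' with ovarian arrest, plus group-level mean and SEM on the proportion
#' scale. Inference is done on the arcsine-transformed scale
#' ([dormancy_anova()]); display stays on the untransformed percent scale.
#'
#' @param table A [dormancy_table].
#' @return A list of class `dormancy_proportions` with `replicates` (per-vial
#'   `proportion` and `arcsine`) and `groups` (mean, SEM, replicate and fly
#'   counts per genotype, split by photoperiod when present).
#' @export
dormancy_proportions <- function(table) {
  if (!inherits(table, "dormancy_table")) table <- dormancy_table(table)
  reps <- tibble::as_tibble(table)
  reps$proportion <- reps$n_arrested / reps$n_dissected
  reps$arcsine <- arcsine_transform(reps$proportion)
  group_vars <- intersect(c("genotype", "photoperiod"), names(reps))
  groups <- dplyr::summarise(
    dplyr::group_by(reps, dplyr::across(dplyr::all_of(group_vars))),
    n_replicates = dplyr::n(),
    n_dissected = sum(.data$n_dissected),
    n_arrested = sum(.data$n_arrested),
    mean_proportion = mean(.data$proportion),
    sem_proportion = sem(.data$proportion),
    .groups = "drop"
  )
  structure(list(replicates = reps, groups = groups),
            class = "dormancy_proportions")
}

#' Arcsine square-root transform for proportions
#'
#' The variance-stabilizing transform `asin(sqrt(p))`, in radians, applied to
#' replicate-level proportions before ANOVA. Maps `[0, 1]` onto `[0, pi/2]`
#' and is strictly increasing.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Transformed values in radians.
#' @export
arcsine_transform <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    stop_validation("`p` must be finite numeric")
  }
  if (any(p < 0 | p > 1)) stop_validation("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

anova_tidy <- function(fit) {
  s <- summary(fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(s)),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    meansq = s$`Mean Sq`,
    statistic = s$`F value`,
    p_value = s$`Pr(>F)`
  )
}

#' One-way ANOVA with Tukey HSD on arcsine-transformed dormancy proportions
#'
#' Transforms per-replicate proportions with `asin(sqrt(p))`, fits a one-way
#' ANOVA across genotypes, and runs Tukey's HSD for all pairwise genotype
#' contrasts (studentized-range adjusted p-values). If every replicate value
#' is identical the F statistic is 0 and p = 1 by convention (no variance to
#' partition).
#'
#' @param table A [dormancy_table] (photoperiod, if present, is ignored here;
#'   use [anova_twofactor()] for the factorial analysis).
#' @return A list of class `dormancy_analysis` with `proportions`, the
#'   `anova` table, and the `tukey` pairwise table (difference on the
#'   transformed scale, adjusted p, significance tier).
#' @export
anova_oneway_tukey <- function(table) {
  props <- dormancy_proportions(table)
  reps <- props$replicates
  counts <- table(reps$genotype)
  if (length(counts) < 2L) stop_validation("need at least 2 genotypes")
  if (any(counts < 2L)) {
    stop_validation(sprintf(
      "genotype(s) with a single replicate cannot enter ANOVA: %s",
      paste(names(counts)[counts < 2L], collapse = ", ")
    ))
  }
  df <- data.frame(y = reps$arcsine, genotype = factor(reps$genotype))
  if (isTRUE(all.equal(stats::var(df$y), 0)) || stats::var(df$y) == 0) {
    k <- nlevels(df$genotype); n <- nrow(df)
    anova_tab <- tibble::tibble(
      term = c("genotype", "Residuals"),
      df = c(k - 1L, n - k),
      sumsq = c(0, 0), meansq = c(0, 0),
      statistic = c(0, NA_real_), p_value = c(1, NA_real_)
    )
    pairs <- utils::combn(levels(df$genotype), 2L)
    tukey <- tibble::tibble(
      pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = 0, lwr = 0, upr = 0, p_adj = 1, tier = "ns"
    )
  } else {
    fit <- aov(y ~ genotype, data = df)
    anova_tab <- anova_tidy(fit)
    tk <- TukeyHSD(fit)$genotype
    tukey <- tibble::tibble(
      pair = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"],
      tier = as.character(significance_tier(tk[, "p adj"]))
    )
  }
  structure(
    list(proportions = props, anova = anova_tab, tukey = tukey,
         transform = "asin(sqrt(p)) [radians]", design = "one-way"),
    class = "dormancy_analysis"
  )
}

#' Two-factor ANOVA (genotype x photoperiod) on arcsine-transformed proportions
#'
#' Fits the full factorial model `y ~ genotype * photoperiod` on
#' arcsine-transformed replicate proportions, reporting main-effect and
#' interaction F tests. The design must have every genotype x photoperiod
#' cell filled with at least 2 replicates; balanced designs use the standard
#' sequential decomposition (which coincides with all SS types when
#' balanced), mildly unbalanced designs use Type-II sums of squares.
#'
#' @param table A [dormancy_table] with a `photoperiod` column.
#' @return A `dormancy_analysis` with the two-way `anova` table and Tukey HSD
#'   tables for both main factors.
#' @export
anova_twofactor <- function(table) {
  props <- dormancy_proportions(table)
  reps <- props$replicates
  if (!"photoperiod" %in% names(reps)) {
    stop_validation("two-factor analysis requires a `photoperiod` column")
  }
  df <- data.frame(y = reps$arcsine, genotype = factor(reps$genotype),
                   photoperiod = factor(reps$photoperiod))
  if (nlevels(df$genotype) < 2L || nlevels(df$photoperiod) < 2L) {
    stop_validation("need >= 2 levels of both genotype and photoperiod")
  }
  cell <- table(df$genotype, df$photoperiod)
  if (any(cell == 0L)) stop_validation("empty genotype x photoperiod cell")
  if (any(cell < 2L)) stop_validation("every design cell needs >= 2 replicates")
  balanced <- length(unique(as.vector(cell))) == 1L

  fit <- aov(y ~ genotype * photoperiod, data = df)
  if (balanced) {
    anova_tab <- anova_tidy(fit)
  } else {
    anova_tab <- type2_anova(df)
  }
  tk <- TukeyHSD(fit, which = c("genotype", "photoperiod"))
  tidy_tk <- function(m) {
    tibble::tibble(pair = rownames(m), diff = m[, "diff"], lwr = m[, "lwr"],
                   upr = m[, "upr"], p_adj = m[, "p adj"],
                   tier = as.character(significance_tier(m[, "p adj"])))
  }
  structure(
    list(proportions = props, anova = anova_tab,
         tukey = list(genotype = tidy_tk(tk$genotype),
                      photoperiod = tidy_tk(tk$photoperiod)),
         transform = "asin(sqrt(p)) [radians]",
         design = if (balanced) "two-way (balanced)" else "two-way (type II)"),
    class = "dormancy_analysis"
  )
}

# Type-II sums of squares (car) for mildly unbalanced factorial designs.
type2_anova <- function(df) {
  a2 <- car::Anova(stats::lm(y ~ genotype * photoperiod, data = df), type = 2)
  tibble::tibble(
    term = trimws(rownames(a2)),
    df = a2$Df,
    sumsq = a2$`Sum Sq`,
    meansq = a2$`Sum Sq` / a2$Df,
    statistic = a2$`F value`,
    p_value = a2$`Pr(>F)`
  )
}

#' @export
print.dormancy_analysis <- function(x, ...) {
  cat(sprintf("<dormancy_analysis> %s ANOVA on %s\n", x$design, x$transform))
  print(x$anova)
  invisible(x)
}

#' Relative expression ratios by the 2^-ddCt method
#'
#' Per sample: `dCt = Ct(target) - Ct(reference)`; `ddCt = dCt - mean dCt of
#' the calibrator group`; `ratio = 2^-ddCt`. The calibrator group's geometric
#' mean ratio is 1 by construction. Per-group arithmetic mean ratio and SEM
#' are reported.
#'
#' @param ct Data frame with columns `sample`, `group`, `gene`, `ct` — one
#'   row per (sample, gene) threshold-cycle measurement.
#' @param target Name of the target gene.
#' @param reference Name of the reference (housekeeping) gene, e.g. `"rp49"`.
#' @param calibrator Group label used as the calibrator.
#' @return A list of class `ddct_result` with per-sample `samples`
#'   (`dct`, `ddct`, `ratio`) and per-group `groups` (mean ratio, SEM).
#' @export
ddct_ratios <- function(ct, target, reference, calibrator) {
  ct <- tibble::as_tibble(ct)
  required <- c("sample", "group", "gene", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("Ct table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(ct, .data$gene %in% c(target, reference)),
    id_cols = c("sample", "group"), names_from = "gene", values_from = "ct"
  )
  if (!target %in% names(wide)) {
    stop_validation(sprintf("no Ct values for target gene `%s`", target))
  }
  if (!reference %in% names(wide) || anyNA(wide[[reference]])) {
    stop_validation(sprintf("missing reference (`%s`) Ct for at least one sample",
                            reference))
  }
  if (anyNA(wide[[target]])) {
    stop_validation(sprintf("missing target (`%s`) Ct for at least one sample", target))
  }
  if (!calibrator %in% wide$group) {
    stop_validation(sprintf("calibrator group `%s` not present", calibrator))
  }
  wide$dct <- wide[[target]] - wide[[reference]]
  cal_mean <- mean(wide$dct[wide$group == calibrator])
  wide$ddct <- wide$dct - cal_mean
  wide$ratio <- 2^(-wide$ddct)
  groups <- dplyr::summarise(
    dplyr::group_by(wide, .data$group),
    n = dplyr::n(),
    mean_ratio = mean(.data$ratio),
    sem_ratio = sem(.data$ratio),
    .groups = "drop"
  )
  structure(
    list(samples = wide, groups = groups, target = target,
         reference = reference, calibrator = calibrator),
    class = "ddct_result"
  )
}
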