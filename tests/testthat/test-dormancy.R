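make_dormancy <- function(props, n = 60, photoperiod = NULL) {
  rows <- lapply(names(props), function(g) {
    tibble::tibble(
      genotype = g,
      replicate = sprintf("r%d", seq_along(props[[g]])),
      n_dissected = n,
      n_arrested = as.integer(round(props[[g]] * n))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(photoperiod)) out$photoperiod <- photoperiod
  dormancy_table(out)
}

test_that("replicate proportions and group summaries follow direct arithmetic", {
  tab <- make_dormancy(list(A = c(0.4, 0.5, 0.6), B = c(0, 1, 0.5)), n = 60)
  props <- dormancy_proportions(tab)
  expect_equal(props$replicates$proportion,
               c(0.4, 0.5, 0.6, 0, 1, 0.5))
  ga <- props$groups[props$groups$genotype == "A", ]
  expect_equal(ga$mean_proportion, 0.5)
  expect_equal(ga$sem_proportion, sd(c(0.4, 0.5, 0.6)) / sqrt(3))
  expect_equal(ga$sem_proportion, 0.0577, tolerance = 1e-3)
})

test_that("arcsine transform has the closed-form values, bounds, monotonicity", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), pi / 4)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_true(all(arcsine_transform(p) >= 0 & arcsine_transform(p) <= pi / 2))
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]",
               class = "ipcquant_validation_error")
  expect_error(arcsine_transform(-0.1), "\\[0, 1\\]",
               class = "ipcquant_validation_error")
})

test_that("one-way arcsine ANOVA: degenerate, t^2 = F, and Tukey conservativeness", {
  # all groups identical: F = 0, p = 1 by convention
  same <- make_dormancy(list(A = c(0.5, 0.5), B = c(0.5, 0.5)))
  out <- anova_oneway_tukey(same)
  expect_equal(out$anova$statistic[1], 0)
  expect_equal(out$anova$p_value[1], 1)

  # balanced two-group: F equals the square of the two-sample t statistic
  tab <- make_dormancy(list(A = c(0.30, 0.35, 0.40, 0.32, 0.38),
                            B = c(0.55, 0.60, 0.52, 0.58, 0.62)))
  out <- anova_oneway_tukey(tab)
  y <- arcsine_transform(dormancy_proportions(tab)$replicates$proportion)
  tt <- t.test(y[1:5], y[6:10], var.equal = TRUE)
  expect_equal(out$anova$statistic[1], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(out$anova$p_value[1], tt$p.value, tolerance = 1e-10)
  expect_equal(sum(out$anova$df), 10 - 1)

  # >= 3 groups: Tukey-adjusted p never undercuts the unadjusted pairwise p
  # from the same pooled model (t on the pooled MSE with N - k df)
  tab3 <- make_dormancy(list(A = c(0.30, 0.35, 0.40, 0.33),
                             B = c(0.45, 0.50, 0.42, 0.48),
                             C = c(0.60, 0.66, 0.58, 0.63)))
  out3 <- anova_oneway_tukey(tab3)
  y3 <- arcsine_transform(dormancy_proportions(tab3)$replicates$proportion)
  g3 <- factor(rep(c("A", "B", "C"), each = 4))
  mse <- sum(stats::residuals(aov(y3 ~ g3))^2) / (12 - 3)
  for (i in seq_len(nrow(out3$tukey))) {
    pair <- strsplit(out3$tukey$pair[i], "-")[[1]]
    tstat <- (mean(y3[g3 == pair[1]]) - mean(y3[g3 == pair[2]])) /
      sqrt(mse * (1 / 4 + 1 / 4))
    raw <- 2 * pt(-abs(tstat), df = 12 - 3)
    expect_gte(out3$tukey$p_adj[i], raw - 1e-9)
  }

  single <- make_dormancy(list(A = 0.4, B = c(0.5, 0.6)))
  expect_error(anova_oneway_tukey(single), "single replicate",
               class = "ipcquant_validation_error")
})

test_that("two-factor ANOVA decomposes SS, detects effects, flags bad designs", {
  # cell means exactly additive on the transformed scale, with a replicate
  # offset pattern shared across cells so the interaction contrast is zero;
  # huge vial size keeps count quantization far below the replicate spread
  cells <- expand.grid(genotype = c("wt", "mut"), photoperiod = c("LD", "SD"))
  delta <- c(-2, -1, 0, 1, 2) * 0.01
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    mu <- 0.5 + 0.15 * (cells$genotype[i] == "mut") +
      0.10 * (cells$photoperiod[i] == "SD")
    y <- mu + delta
    rows[[i]] <- tibble::tibble(
      genotype = as.character(cells$genotype[i]),
      photoperiod = as.character(cells$photoperiod[i]),
      replicate = sprintf("r%d", 1:5),
      n_dissected = 1000000L,
      n_arrested = as.integer(round(sin(y)^2 * 1000000))
    )
  }
  tab <- dormancy_table(dplyr::bind_rows(rows))
  out <- anova_twofactor(tab)
  a <- out$anova
  expect_equal(a$term[1:3], c("genotype", "photoperiod", "genotype:photoperiod"))
  expect_gt(a$p_value[a$term == "genotype:photoperiod"], 0.99)
  expect_lt(a$p_value[a$term == "genotype"], 1e-6)
  # balanced decomposition: SS_total = SS_A + SS_B + SS_AB + SS_error
  y_all <- arcsine_transform(dormancy_proportions(tab)$replicates$proportion)
  ss_total <- sum((y_all - mean(y_all))^2)
  expect_equal(sum(a$sumsq), ss_total, tolerance = 1e-8 * ss_total)
  expect_equal(sum(a$df), length(y_all) - 1)

  # identical cell means: all F ~ 0
  flat <- dormancy_table(tibble::tibble(
    genotype = rep(c("wt", "mut"), each = 4),
    photoperiod = rep(rep(c("LD", "SD"), each = 2), times = 2),
    replicate = sprintf("r%d", 1:8),
    n_dissected = 60L,
    n_arrested = rep(c(30L, 31L), times = 4)
  ))
  outf <- anova_twofactor(flat)
  expect_lt(max(outf$anova$statistic[1:3]), 1e-10)

  # empty cell is rejected
  miss <- dplyr::bind_rows(rows)[-(1:5), ]
  expect_error(anova_twofactor(dormancy_table(miss)), "empty",
               class = "ipcquant_validation_error")

  # power: genotype shift of 0.3 rad at n = 5/cell, sd = 0.1 is detected
  # almost always (simulated directly on the transformed scale)
  detect <- logical(300)
  set.seed(17)
  for (i in seq_along(detect)) {
    y <- c(rnorm(10, 0.6, 0.1), rnorm(10, 0.9, 0.1))
    sim <- tibble::tibble(
      genotype = rep(c("wt", "mut"), each = 10),
      photoperiod = rep(rep(c("LD", "SD"), each = 5), times = 2),
      replicate = sprintf("r%d", 1:20),
      n_dissected = 200L,
      n_arrested = as.integer(round(sin(pmin(pmax(y, 0), pi / 2))^2 * 200))
    )
    res <- anova_twofactor(dormancy_table(sim))
    detect[i] <- res$anova$p_value[res$anova$term == "genotype"] < 0.05
  }
  expect_gt(mean(detect), 0.9)
})

test_that("2^-ddCt ratios match closed forms and normalize the calibrator", {
  ct <- tibble::tibble(
    sample = rep(sprintf("s%d", 1:6), each = 2),
    group = rep(c("ctrl", "ctrl", "ctrl", "kd", "kd", "kd"), each = 2),
    gene = rep(c("snpfr", "rp49"), times = 6),
    ct = c(20, 18, 21, 19, 22, 20,   # ctrl: dCt = 2 each
           21, 18, 19.5, 19.5, 24, 21)  # kd: dCt = 3, 0, 3
  )
  out <- ddct_ratios(ct, target = "snpfr", reference = "rp49",
                     calibrator = "ctrl")
  # ddCt = 0 -> ratio 1; +1 -> 0.5; -2 -> 4
  expect_equal(out$samples$ratio[out$samples$group == "ctrl"], rep(1, 3))
  expect_equal(out$samples$ratio[out$samples$sample == "s4"], 0.5)
  expect_equal(out$samples$ratio[out$samples$sample == "s5"], 4)
  # calibrator geometric mean ratio is 1 by construction
  cal <- out$samples$ratio[out$samples$group == "ctrl"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)
  expect_true(all(out$samples$ratio > 0))

  missing_ref <- dplyr::filter(ct, !(sample == "s2" & gene == "rp49"))
  expect_error(ddct_ratios(missing_ref, "snpfr", "rp49", "ctrl"),
               "reference", class = "ipcquant_validation_error")
})
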