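test_that("background correction is elementwise with a floored degenerate path", {
  expect_equal(background_correct(c(100, 110), 10), c(90, 100))
  expect_equal(background_correct(c(120, 130, 125), c(20, 20, 20)),
               c(100, 110, 105))
  # fully cancelled channel is degenerate, partial cancellation floors + warns
  expect_error(background_correct(c(100), c(100)), "degenerate",
               class = "ipcquant_validation_error")
  expect_warning(out <- background_correct(c(100, 5), c(10, 5)), "floored")
  expect_equal(out, c(90, 1e-9))
  expect_error(background_correct(c(1, 2), c(1, 2, 3)), "scalar or match",
               class = "ipcquant_validation_error")
})

test_that("spillover subtraction removes the stated CFP fraction from YFP", {
  expect_identical(formals(spillover_correct)$k, 0.357)
  expect_equal(spillover_correct(100, 0), 100)
  expect_equal(spillover_correct(120, 50), 120 - 0.357 * 50)
  expect_equal(spillover_correct(c(200, 210), c(100, 100), k = 0.5),
               c(150, 160))
  expect_error(spillover_correct(1, 1, k = 1), "< 1",
               class = "ipcquant_validation_error")
})

test_that("iFRET is CFP over spillover-corrected YFP with invalid-frame policy", {
  expect_equal(as.numeric(compute_ifret(0, 100)), 0)
  expect_equal(as.numeric(compute_ifret(50, 120)), 50 / (120 - 0.357 * 50))

  # singular denominator: frame marked invalid but ROI survives below 10%
  cfp <- c(rep(50, 19), 100)
  yfp <- c(rep(120, 19), 35.7)
  out <- compute_ifret(cfp, yfp)
  expect_true(is.na(out[20]))
  expect_equal(attr(out, "n_invalid"), 1L)

  # more than 10% invalid frames rejects the ROI
  expect_error(compute_ifret(c(100, 100, 50), c(35.7, 35.7, 120)),
               "rejected", class = "ipcquant_validation_error")
})

test_that("baseline normalization gives percent change with rejection rules", {
  w <- analysis_windows(baseline = c(0, 3), long = c(3, 5), short = c(3, 4))
  t <- 0:5
  # constant trace normalizes to identically 0%
  out <- normalize_to_baseline(rep(0.5, 6), t, w)
  expect_equal(out$values, rep(0, 6))
  expect_equal(out$baseline_mean, 0.5)
  # worked percent changes
  out <- normalize_to_baseline(c(0.5, 0.5, 0.5, 0.5, 0.6, 0.45), t, w)
  expect_equal(out$values[4:6], c(0, 20, -10))
  # a +10% excursion from baseline mean 0.50
  out <- normalize_to_baseline(c(0.5, 0.5, 0.5, 0.55), 0:3,
                               analysis_windows(c(0, 3), c(3, 3), c(3, 3)))
  expect_equal(out$values[4], 10)

  w2 <- analysis_windows(baseline = c(0, 2), long = c(2, 5), short = c(2, 3))
  expect_error(normalize_to_baseline(c(0.5, 0.5, 0.6, 0.7), 0:3, w2),
               "fewer than 3", class = "ipcquant_validation_error")
  expect_error(normalize_to_baseline(c(-1, -1, -1, 0), 0:3, w),
               "not positive", class = "ipcquant_validation_error")
})

test_that("windowed maxima take the closed-window maximum by time membership", {
  t <- seq(0, 100, by = 10)
  vals <- rep(0, length(t))
  expect_equal(max_response(vals, t, c(0, 100)), 0)
  vals[6] <- 12.5
  expect_equal(max_response(vals, t, c(20, 80)), 12.5)
  # endpoint inclusion: frame exactly at the window edge counts
  expect_equal(max_response(vals, t, c(50, 50)), 12.5)
  expect_error(max_response(vals, t, c(101, 200)), "no valid frames",
               class = "ipcquant_validation_error")
})

test_that("dF/F0 matches its defining arithmetic and bounds", {
  w <- analysis_windows(baseline = c(0, 3), long = c(3, 6), short = c(3, 4))
  t <- 0:6
  gfp <- c(100, 100, 100, 110, 100, 50, 1e-12)
  out <- delta_f_over_f(gfp, t, w)
  expect_equal(out$baseline_mean, 100)
  expect_equal(out$values[4], 10)   # F0=100, Fn=110 -> +10%
  expect_equal(out$values[1], 0)    # Fn = F0 -> 0%
  expect_equal(out$values[7], -100, tolerance = 1e-9)  # extinction bound
})

test_that("full chain equals the frame-by-frame oracle and is scale invariant", {
  set.seed(101)
  for (i in 1:100) {
    tr <- random_toy_trace()
    o <- chain_oracle(tr)
    p <- chain_pipeline(tr)
    expect_equal(p$norm, o$norm, tolerance = 1e-12)
    expect_equal(p$max_long, o$max_long, tolerance = 1e-12)
    expect_equal(p$max_short, o$max_short, tolerance = 1e-12)

    # multiplying both raw channels and backgrounds by c > 0 leaves the
    # normalized trace unchanged
    cmult <- exp(runif(1, -2, 4))
    scaled <- tr
    scaled$cfp_raw <- tr$cfp_raw * cmult
    scaled$yfp_raw <- tr$yfp_raw * cmult
    scaled$bg <- tr$bg * cmult
    ps <- chain_pipeline(scaled)
    expect_equal(ps$norm, p$norm, tolerance = 1e-10)

    # window nesting: short window is a subset of the long window
    expect_gte(p$max_long, p$max_short - 1e-12)
  }
})

test_that("treatment summaries average across neurons on a common grid", {
  w <- analysis_windows(baseline = c(0, 12), long = c(10, 20), short = c(10, 15))
  base <- toy_trace_table()
  x <- roi_trace_set(base)
  resp <- quantify_fret(x, windows = w)
  s <- summarize_treatment(resp)
  # identical neurons -> SEM exactly 0 at every frame
  expect_true(all(s$traces$sem == 0))
  expect_equal(s$counts$n_neurons, 3L)

  # score vector mean and SEM from maxima {8, 10, 12}
  fake <- resp
  fake$scores$max_long <- c(8, 10, 12)
  s2 <- summarize_treatment(fake)
  v <- score_vectors(s2, "long")$PDF
  expect_equal(mean(v), 10)
  expect_equal(sd(v) / sqrt(3), 2 / sqrt(3))

  # ragged trace lengths truncate to the common grid with a warning
  ragged <- base[!(base$roi_id == "r3" & base$t == 20), ]
  respr <- quantify_fret(roi_trace_set(ragged), windows = w)
  expect_warning(sr <- summarize_treatment(respr), "common time grid")
  expect_false(20 %in% sr$traces$t)

  # design enforcement
  d <- treatment_design(c("HL3", "PDF"), c("negative_control", "experimental"))
  expect_warning(summarize_treatment(resp, design = d), "0 neurons")
  d2 <- treatment_design("HL3", "negative_control")
  expect_error(summarize_treatment(resp, design = d2), "not in design",
               class = "ipcquant_validation_error")
})
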