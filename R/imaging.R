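#' Analysis windows for baseline normalization and response scoring
#'
#' Times are in seconds. The baseline window is half-open `[start, end)` and
#' must precede bath application; the long and short response windows are
#' closed intervals. Defaults follow the standard protocol for this kind of
#' bath-application experiment: ~100 s of baseline before application, a long
#' scoring window of 100-1000 s capturing the slow cAMP rise, and a short
#' window of 100-200 s capturing the immediate response.
#'
#' @param baseline Numeric length-2, baseline window `[start, end)` in seconds.
#' @param long Numeric length-2, long response window (closed) in seconds.
#' @param short Numeric length-2, short response window (closed) in seconds.
#' @return A list of class `analysis_windows`.
#' @export
analysis_windows <- function(baseline = c(0, 100), long = c(100, 1000),
                             short = c(100, 200)) {
  for (w in list(baseline = baseline, long = long, short = short)) {
    if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w))) {
      stop_validation("each window must be a finite numeric vector of length 2")
    }
  }
  if (baseline[2] <= baseline[1]) stop_validation("baseline window is empty")
  if (long[2] < long[1]) stop_validation("long window is empty")
  if (short[2] < short[1]) stop_validation("short window is empty")
  structure(list(baseline = as.numeric(baseline), long = as.numeric(long),
                 short = as.numeric(short)),
            class = "analysis_windows")
}

#' Background-correct a raw fluorescence channel
#'
#' Subtracts a background trace (or scalar) element-wise from a raw intensity
#' trace. Corrected values are floored at a small positive `eps` so that
#' downstream ratios never divide by zero; a trace whose corrected values are
#' all at the floor is rejected as degenerate.
#'
#' @param raw Numeric vector of raw intensities.
#' @param background Numeric vector of the same length, or a scalar.
#' @param eps Positive floor applied to corrected intensities (channel units).
#' @return Numeric vector of corrected intensities.
#' @export
background_correct <- function(raw, background = 0, eps = 1e-9) {
  if (!is.numeric(raw) || length(raw) == 0L) stop_validation("`raw` must be numeric")
  if (length(background) == 1L) background <- rep(background, length(raw))
  if (length(background) != length(raw)) {
    stop_validation("`background` must be a scalar or match the trace length")
  }
  corrected <- raw - background
  floored <- corrected < eps
  if (all(floored)) {
    stop_validation("background correction left no signal: corrected channel is degenerate")
  }
  if (any(floored)) {
    warn(sprintf("%d corrected frame(s) floored at eps = %g", sum(floored), eps))
    corrected[floored] <- eps
  }
  corrected
}

#' Subtract CFP spillover from the YFP channel
#'
#' A fraction `k` of CFP emission is detected in the YFP channel
#' (bleed-through); it is removed by subtracting `k * cfp` element-wise. The
#' default spillover fraction is 0.357 (35.7% of the CFP signal), as
#' determined for the imaging setup this pipeline targets.
#'
#' @param yfp,cfp Background-corrected channel traces of equal length.
#' @param k Spillover fraction, `0 <= k < 1`.
#' @return Numeric vector `yfp - k * cfp`. Non-positive results are permitted
#'   here; [compute_ifret()] flags them as invalid frames.
#' @export
spillover_correct <- function(yfp, cfp, k = 0.357) {
  assert_number(k, "k", lower = 0)
  if (k >= 1) stop_validation("spillover fraction `k` must be < 1")
  if (length(yfp) != length(cfp)) stop_validation("`yfp` and `cfp` must have equal length")
  yfp - k * cfp
}

#' Compute the inverse FRET (cAMP) trace
#'
#' `iFRET = CFP / (YFP - k * CFP)`, computed frame-wise on background-corrected
#' channels. iFRET rises as cAMP rises (the sensor's FRET decreases). Frames
#' whose spillover-corrected denominator falls at or below `eps` are marked
#' invalid (`NA`) and excluded from baseline and maxima; an ROI with more than
#' `max_invalid_frac` invalid frames is rejected.
#'
#' @param cfp,yfp Background-corrected channel traces of equal length.
#' @param k Spillover fraction (default 0.357).
#' @param eps Positive denominator floor below which a frame is invalid.
#' @param max_invalid_frac Maximum tolerated fraction of invalid frames
#'   before the ROI is rejected (default 0.1).
#' @return Numeric iFRET trace with `NA` at invalid frames and an
#'   `n_invalid` attribute.
#' @export
compute_ifret <- function(cfp, yfp, k = 0.357, eps = 1e-9,
                          max_invalid_frac = 0.1) {
  if (length(yfp) != length(cfp)) stop_validation("`yfp` and `cfp` must have equal length")
  denom <- spillover_correct(yfp, cfp, k = k)
  valid <- is.finite(denom) & denom > eps & is.finite(cfp)
  n_invalid <- sum(!valid)
  if (n_invalid > max_invalid_frac * length(cfp)) {
    stop_validation(sprintf(
      "ROI rejected: %d of %d frames (%.1f%%) have non-positive iFRET denominator",
      n_invalid, length(cfp), 100 * n_invalid / length(cfp)
    ))
  }
  out <- rep(NA_real_, length(cfp))
  out[valid] <- cfp[valid] / denom[valid]
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Normalize a signal trace to its pre-application baseline
#'
#' Divides by the mean signal over the baseline window and expresses the
#' trace as percent change: `normalized(t) = (signal(t) / baseline_mean - 1) * 100`.
#'
#' @param signal Numeric signal trace (`NA` marks invalid frames).
#' @param t Time in seconds, same length as `signal`.
#' @param windows An [analysis_windows] object.
#' @return A list with `values` (percent-change trace, `NA` preserved) and
#'   `baseline_mean`.
#' @export
normalize_to_baseline <- function(signal, t, windows) {
  if (length(signal) != length(t)) stop_validation("`signal` and `t` must have equal length")
  b <- windows$baseline
  in_base <- t >= b[1] & t < b[2] & !is.na(signal)
  if (sum(in_base) < 3L) {
    stop_validation("ROI rejected: fewer than 3 valid baseline frames")
  }
  baseline_mean <- mean(signal[in_base])
  if (!is.finite(baseline_mean) || baseline_mean <= 0) {
    stop_validation("ROI rejected: baseline mean is not positive")
  }
  list(values = as.vector((signal / baseline_mean - 1) * 100),
       baseline_mean = baseline_mean)
}

#' Maximum response within a time window
#'
#' The maximum of a baseline-normalized trace over frames with
#' `t0 <= t <= t1` (closed window, membership by time, not frame index).
#'
#' @param values Normalized trace (percent change); `NA` frames are skipped.
#' @param t Time in seconds.
#' @param window Numeric length-2 closed window `[t0, t1]` in seconds.
#' @return Maximum percent change (scalar).
#' @export
max_response <- function(values, t, window) {
  if (length(values) != length(t)) stop_validation("`values` and `t` must have equal length")
  if (!is.numeric(window) || length(window) != 2L) {
    stop_validation("`window` must be numeric of length 2")
  }
  sel <- t >= window[1] & t <= window[2] & !is.na(values)
  if (!any(sel)) stop_validation("no valid frames inside the response window")
  max(values[sel])
}

#' Calcium dF/F0 trace from a single-channel sensor
#'
#' `dF/F0 = (F_n - F0) / F0 * 100` with `F0` the mean fluorescence over the
#' baseline window, plus windowed maximum-response scores.
#'
#' @param gfp Background-corrected fluorescence trace.
#' @param t Time in seconds.
#' @param windows An [analysis_windows] object.
#' @return A list with `values` (percent-change trace), `baseline_mean` (F0),
#'   `max_long` and `max_short`.
#' @export
delta_f_over_f <- function(gfp, t, windows) {
  norm <- normalize_to_baseline(gfp, t, windows)
  list(
    values = norm$values,
    baseline_mean = norm$baseline_mean,
    max_long = max_response(norm$values, t, windows$long),
    max_short = max_response(norm$values, t, windows$short)
  )
}

# Pull per-ROI background vectors, or 0 with a single warning per call.
roi_background <- function(df, bg_col, warned_env) {
  if (bg_col %in% names(df)) return(df[[bg_col]])
  if (!isTRUE(warned_env$warned)) {
    warn(sprintf("no `%s` column: background taken as 0", bg_col))
    warned_env$warned <- TRUE
  }
  0
}

quantify_rois <- function(x, windows, per_roi) {
  stopifnot(inherits(x, "roi_trace_set"))
  if (windows$baseline[2] > attr(x, "application_time") + 1e-9) {
    warn("baseline window extends past the application time")
  }
  df <- tibble::as_tibble(x)
  keys <- dplyr::distinct(df, .data$brain_id, .data$roi_id, .data$treatment)
  traces <- vector("list", nrow(keys))
  scores <- vector("list", nrow(keys))
  rejected <- vector("list", nrow(keys))
  split_key <- paste(df$brain_id, df$roi_id, sep = "\r")
  chunks <- split(df, factor(split_key, levels = unique(split_key)))
  for (i in seq_along(chunks)) {
    roi <- chunks[[i]]
    res <- tryCatch(per_roi(roi), ipcquant_validation_error = function(e) e)
    if (inherits(res, "error")) {
      rejected[[i]] <- tibble::tibble(
        brain_id = roi$brain_id[1], roi_id = roi$roi_id[1],
        treatment = roi$treatment[1], reason = conditionMessage(res)
      )
      warn(sprintf("ROI %s/%s rejected: %s", roi$brain_id[1], roi$roi_id[1],
                   conditionMessage(res)))
    } else {
      traces[[i]] <- res$trace
      scores[[i]] <- res$score
    }
  }
  list(
    traces = dplyr::bind_rows(traces),
    scores = dplyr::bind_rows(scores),
    rejected = dplyr::bind_rows(rejected)
  )
}

#' Quantify cAMP (inverse FRET) responses for every ROI
#'
#' Runs the full per-neuron chain on a dual-channel trace set: background
#' correction of CFP and YFP, CFP-spillover subtraction from YFP, frame-wise
#' `iFRET = CFP / (YFP - k*CFP)`, percent-change normalization to the baseline
#' window, and windowed maximum-response scores. ROIs that fail (degenerate
#' channels, too many invalid frames, non-positive or too-short baseline) are
#' excluded and reported in `$rejected` with the reason.
#'
#' @param x An [roi_trace_set] with `cfp` and `yfp` columns.
#' @param windows An [analysis_windows] object.
#' @param k Spillover fraction (default 0.357).
#' @param eps Floor for corrected intensities and ratio denominators.
#' @param max_invalid_frac Per-ROI tolerance for invalid iFRET frames.
#' @return A list of class `normalized_responses` with `traces`
#'   (brain_id, roi_id, treatment, t, value), `scores` (one row per neuron
#'   with `baseline_mean`, `max_long`, `max_short`, `n_invalid`), `rejected`,
#'   the signal kind and the windows used.
#' @export
quantify_fret <- function(x, windows = analysis_windows(), k = 0.357,
                          eps = 1e-9, max_invalid_frac = 0.1) {
  if (!all(c("cfp", "yfp") %in% names(x))) {
    stop_validation("FRET quantification requires `cfp` and `yfp` columns")
  }
  warned_cfp <- new.env(); warned_yfp <- new.env()
  per_roi <- function(roi) {
    cfp <- background_correct(roi$cfp, roi_background(roi, "bg_cfp", warned_cfp),
                              eps = eps)
    yfp <- background_correct(roi$yfp, roi_background(roi, "bg_yfp", warned_yfp),
                              eps = eps)
    ifret <- compute_ifret(cfp, yfp, k = k, eps = eps,
                           max_invalid_frac = max_invalid_frac)
    norm <- normalize_to_baseline(ifret, roi$t, windows)
    list(
      trace = tibble::tibble(
        brain_id = roi$brain_id[1], roi_id = roi$roi_id[1],
        treatment = roi$treatment[1], t = roi$t, value = norm$values
      ),
      score = tibble::tibble(
        brain_id = roi$brain_id[1], roi_id = roi$roi_id[1],
        treatment = roi$treatment[1],
        baseline_mean = norm$baseline_mean,
        max_long = max_response(norm$values, roi$t, windows$long),
        max_short = max_response(norm$values, roi$t, windows$short),
        n_invalid = attr(ifret, "n_invalid")
      )
    )
  }
  out <- quantify_rois(x, windows, per_roi)
  structure(c(out, list(signal = "iFRET", windows = windows, k = k)),
            class = "normalized_responses")
}

#' Quantify calcium (dF/F0) responses for every ROI
#'
#' Single-channel analogue of [quantify_fret()]: background correction of the
#' GFP channel followed by percent-change dF/F0 normalization and windowed
#' maximum-response scores.
#'
#' @param x An [roi_trace_set] with a `gfp` column.
#' @param windows An [analysis_windows] object.
#' @param eps Floor for corrected intensities.
#' @return A `normalized_responses` list (signal kind `"dFoF"`).
#' @export
quantify_calcium <- function(x, windows = analysis_windows(), eps = 1e-9) {
  if (!"gfp" %in% names(x)) {
    stop_validation("calcium quantification requires a `gfp` column")
  }
  warned <- new.env()
  per_roi <- function(roi) {
    gfp <- background_correct(roi$gfp, roi_background(roi, "bg_gfp", warned),
                              eps = eps)
    dff <- delta_f_over_f(gfp, roi$t, windows)
    list(
      trace = tibble::tibble(
        brain_id = roi$brain_id[1], roi_id = roi$roi_id[1],
        treatment = roi$treatment[1], t = roi$t, value = dff$values
      ),
      score = tibble::tibble(
        brain_id = roi$brain_id[1], roi_id = roi$roi_id[1],
        treatment = roi$treatment[1],
        baseline_mean = dff$baseline_mean,
        max_long = dff$max_long,
        max_short = dff$max_short,
        n_invalid = 0L
      )
    )
  }
  out <- quantify_rois(x, windows, per_roi)
  structure(c(out, list(signal = "dFoF", windows = windows)),
            class = "normalized_responses")
}

new_treatment_summary <- function(traces, scores, counts) {
  structure(list(traces = traces, scores = scores, counts = counts),
            class = "treatment_summary")
}

#' Average normalized responses per treatment
#'
#' Computes, for each treatment, the point-wise mean and SEM of the
#' normalized per-neuron traces on a common time grid, together with the
#' vectors of per-neuron maximum-response scores and the neuron and brain
#' counts. SEM is computed across neurons, matching how such experiments are
#' usually reported. Neurons with unequal trace lengths are truncated to the
#' common grid (the intersection of time points), with a warning.
#'
#' @param responses A `normalized_responses` object from [quantify_fret()] or
#'   [quantify_calcium()].
#' @param design Optional [treatment_design]; when given, every response
#'   treatment must appear in the design, and design treatments with no
#'   surviving neurons are dropped with a warning.
#' @return A list of class `treatment_summary` with `traces`
#'   (treatment, t, mean, sem, n), `scores` and `counts`.
#' @export
summarize_treatment <- function(responses, design = NULL) {
  if (!inherits(responses, "normalized_responses")) {
    stop_validation("`responses` must come from quantify_fret()/quantify_calcium()")
  }
  scores <- responses$scores
  traces <- responses$traces
  if (nrow(scores) == 0L) stop_validation("no surviving neurons to summarize")
  if (!is.null(design)) {
    unknown <- setdiff(unique(scores$treatment), design$treatment)
    if (length(unknown) > 0L) {
      stop_validation(sprintf("treatment(s) not in design: %s",
                              paste(unknown, collapse = ", ")))
    }
    empty <- setdiff(design$treatment, unique(scores$treatment))
    if (length(empty) > 0L) {
      warn(sprintf("treatment(s) with 0 neurons excluded: %s",
                   paste(empty, collapse = ", ")))
    }
  }

  # common time grid = time points present in every neuron
  key <- paste(traces$brain_id, traces$roi_id, sep = "\r")
  grid <- Reduce(intersect, split(traces$t, key))
  if (length(grid) < length(unique(traces$t))) {
    warn("unequal trace lengths: truncated to the common time grid")
  }
  common <- dplyr::filter(traces, .data$t %in% grid)
  trace_summary <- dplyr::summarise(
    dplyr::group_by(common, .data$treatment, .data$t),
    mean = mean(.data$value, na.rm = TRUE),
    sem = sem(.data$value),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  trace_summary <- dplyr::arrange(trace_summary, .data$treatment, .data$t)
  counts <- dplyr::summarise(
    dplyr::group_by(scores, .data$treatment),
    n_neurons = dplyr::n(),
    n_brains = length(unique(.data$brain_id)),
    .groups = "drop"
  )
  new_treatment_summary(
    traces = trace_summary,
    scores = dplyr::arrange(scores, .data$treatment, .data$brain_id, .data$roi_id),
    counts = counts
  )
}

#' @export
print.treatment_summary <- function(x, ...) {
  cat("<treatment_summary>\n")
  print(x$counts)
  invisible(x)
}

#' Extract per-neuron score vectors from a treatment summary
#'
#' @param summary A [treatment_summary].
#' @param window `"long"` or `"short"` — which windowed maximum to extract.
#' @return A named list of numeric score vectors, one per treatment.
#' @export
score_vectors <- function(summary, window = c("long", "short")) {
  window <- match.arg(window)
  col <- if (window == "long") "max_long" else "max_short"
  split(summary$scores[[col]], summary$scores$treatment)
}
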