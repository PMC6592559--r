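#' Construct and validate an ROI trace set
#'
#' An `roi_trace_set` is the pipeline's raw input: one row per
#' (brain, ROI, frame) with time in seconds and raw fluorescence intensities.
#' FRET (cAMP) experiments carry `cfp` and `yfp` columns; calcium experiments
#' carry `gfp`. Optional `bg_cfp`, `bg_yfp`, `bg_gfp` columns hold background
#' ROI intensities measured alongside the cell-body ROIs; when absent,
#' background is taken as zero during quantification (with a warning).
#'
#' @param data A data frame with columns `brain_id`, `roi_id`, `treatment`,
#'   `t` (seconds) and at least one of `cfp`+`yfp` or `gfp`.
#' @param application_time Bath-application time in seconds. The baseline
#'   window precedes this time point; default 100 s.
#' @param frame_rate Nominal acquisition rate in Hz (default 0.2, i.e. one
#'   frame every 5 s). Frame spacing must be consistent with this rate within
#'   1% (integer multiples of the frame period are allowed, so occasional
#'   dropped frames do not invalidate a recording).
#'
#' @return A tibble of class `roi_trace_set`, sorted by brain, ROI and time,
#'   with `application_time` and `frame_rate` attributes.
#' @export
roi_trace_set <- function(data, application_time = 100, frame_rate = 0.2) {
  data <- tibble::as_tibble(data)
  required <- c("brain_id", "roi_id", "treatment", "t")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "trace table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  has_fret <- all(c("cfp", "yfp") %in% names(data))
  has_ca <- "gfp" %in% names(data)
  if (!has_fret && !has_ca) {
    stop_validation("trace table must contain either `cfp` and `yfp`, or `gfp`")
  }
  assert_number(application_time, "application_time", lower = 0)
  assert_number(frame_rate, "frame_rate", lower = 1e-9)
  if (nrow(data) == 0L) stop_validation("trace table has no rows")

  channels <- intersect(c("cfp", "yfp", "gfp", "bg_cfp", "bg_yfp", "bg_gfp"),
                        names(data))
  for (ch in channels) {
    v <- data[[ch]]
    if (!is.numeric(v)) stop_validation(sprintf("column `%s` must be numeric", ch))
    if (anyNA(v) || any(!is.finite(v))) {
      stop_validation(sprintf("column `%s` contains non-finite values", ch))
    }
    if (any(v < 0)) {
      stop_validation(sprintf("column `%s` contains negative intensities", ch))
    }
  }
  if (!is.numeric(data$t) || any(!is.finite(data$t))) {
    stop_validation("column `t` must be finite numeric seconds")
  }

  data <- dplyr::arrange(data, .data$brain_id, .data$roi_id, .data$t)
  key <- paste(data$brain_id, data$roi_id, sep = "\r")

  # one treatment label per ROI
  n_trt <- tapply(data$treatment, key, function(x) length(unique(x)))
  if (any(n_trt > 1L)) {
    bad <- names(n_trt)[which(n_trt > 1L)[1L]]
    stop_validation(sprintf(
      "ROI %s carries more than one treatment label",
      gsub("\r", "/", bad)
    ))
  }

  # strictly increasing time and frame spacing per ROI
  period <- 1 / frame_rate
  for (k in unique(key)) {
    tt <- data$t[key == k]
    dt <- diff(tt)
    if (any(dt <= 0)) {
      stop_validation(sprintf(
        "time is not strictly increasing within ROI %s (duplicated or unordered frames)",
        gsub("\r", "/", k)
      ))
    }
    if (length(dt) > 0L) {
      mult <- dt / period
      if (any(abs(mult - round(mult)) > 0.01 * pmax(1, round(mult)) | round(mult) < 1)) {
        stop_validation(sprintf(
          "frame spacing within ROI %s is inconsistent with frame_rate = %g Hz (within 1%%)",
          gsub("\r", "/", k), frame_rate
        ))
      }
    }
  }

  structure(
    data,
    class = c("roi_trace_set", class(tibble::tibble())),
    application_time = application_time,
    frame_rate = frame_rate
  )
}

#' @export
print.roi_trace_set <- function(x, ...) {
  key <- paste(x$brain_id, x$roi_id)
  cat(sprintf(
    "<roi_trace_set> %d frames, %d ROIs, %d brains, %d treatment(s); application at %g s, %g Hz\n",
    nrow(x), length(unique(key)), length(unique(x$brain_id)),
    length(unique(x$treatment)),
    attr(x, "application_time"), attr(x, "frame_rate")
  ))
  NextMethod()
}

#' Read an ROI trace table from delimited text
#'
#' Expects a header with columns
#' `brain_id,roi_id,treatment,t,cfp,yfp[,gfp][,bg_cfp,bg_yfp,bg_gfp]`
#' (comma-delimited, `.` decimal). Rows are grouped and time-sorted per ROI
#' and validated; the number of ROIs and brains found is reported.
#'
#' @inheritParams roi_trace_set
#' @param path Path to a CSV file.
#' @param delim Field delimiter (default `","`).
#' @return An [roi_trace_set].
#' @export
read_trace_table <- function(path, application_time = 100, frame_rate = 0.2,
                             delim = ",") {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- read_csv_precise(path, delim = delim,
                          character_cols = c("brain_id", "roi_id", "treatment"))
  x <- roi_trace_set(raw, application_time = application_time,
                     frame_rate = frame_rate)
  key <- paste(x$brain_id, x$roi_id)
  inform(sprintf("read %d ROIs from %d brains (%d frames) from %s",
                 length(unique(key)), length(unique(x$brain_id)), nrow(x),
                 basename(path)))
  x
}

#' Write an ROI trace table to CSV
#'
#' @param x An [roi_trace_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  if (!inherits(x, "roi_trace_set")) stop_validation("`x` must be an roi_trace_set")
  write_csv_precise(tibble::as_tibble(x), path)
  invisible(path)
}

#' Construct and validate a dormancy count table
#'
#' One row per replicate vial: the number of dissected females and the number
#' scored as reproductively arrested (absence of yolk deposition in the
#' ovarian follicles). `photoperiod` is optional and enables the two-factor
#' analysis.
#'
#' @param data A data frame with columns `genotype`, `replicate`,
#'   `n_dissected`, `n_arrested` and optionally `photoperiod`.
#' @return A tibble of class `dormancy_table`.
#' @export
dormancy_table <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("genotype", "replicate", "n_dissected", "n_arrested")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "dormancy table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(data) == 0L) stop_validation("dormancy table has no replicates")
  for (col in c("n_dissected", "n_arrested")) {
    v <- data[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)) || any(v < 0)) {
      stop_validation(sprintf("column `%s` must hold non-negative integer counts", col))
    }
  }
  if (any(data$n_dissected < 1)) {
    stop_validation("every replicate must have n_dissected >= 1")
  }
  if (any(data$n_arrested > data$n_dissected)) {
    stop_validation("n_arrested exceeds n_dissected in at least one replicate")
  }
  structure(data, class = c("dormancy_table", class(tibble::tibble())))
}

#' Read a dormancy count table from CSV
#'
#' Expects a header `genotype[,photoperiod],replicate,n_dissected,n_arrested`.
#'
#' @param path Path to a CSV file.
#' @return A [dormancy_table].
#' @export
read_dormancy_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- read_csv_precise(
    path, character_cols = c("genotype", "photoperiod", "replicate")
  )
  raw$n_dissected <- as.integer(raw$n_dissected)
  raw$n_arrested <- as.integer(raw$n_arrested)
  dormancy_table(raw)
}

#' Write a dormancy count table to CSV
#'
#' @param x A [dormancy_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dormancy_table <- function(x, path) {
  if (!inherits(x, "dormancy_table")) stop_validation("`x` must be a dormancy_table")
  write_csv_precise(tibble::as_tibble(x), path)
  invisible(path)
}

#' Define treatment roles for an experiment
#'
#' Each treatment is assigned a role: exactly one `negative_control`
#' (typically vehicle saline), optionally one or more `positive_control`
#' (e.g. an adenylate cyclase activator for cAMP, a cholinergic agonist for
#' calcium), the rest `experimental`.
#'
#' @param treatment Character vector of treatment labels.
#' @param role Character vector of roles, one of `"negative_control"`,
#'   `"positive_control"`, `"experimental"`.
#' @param description Optional character vector of free-text descriptions.
#' @return A tibble of class `treatment_design`.
#' @export
treatment_design <- function(treatment, role, description = NA_character_) {
  valid_roles <- c("negative_control", "positive_control", "experimental")
  if (length(treatment) != length(role)) {
    stop_validation("`treatment` and `role` must have equal length")
  }
  if (!all(role %in% valid_roles)) {
    stop_validation(sprintf("roles must be one of: %s",
                            paste(valid_roles, collapse = ", ")))
  }
  if (anyDuplicated(treatment)) stop_validation("duplicated treatment labels")
  if (sum(role == "negative_control") != 1L) {
    stop_validation("exactly one treatment must have role `negative_control`")
  }
  structure(
    tibble::tibble(treatment = as.character(treatment), role = role,
                   description = rep_len(description, length(treatment))),
    class = c("treatment_design", class(tibble::tibble()))
  )
}

#' Write treatment summaries to a delimited summary table
#'
#' Serializes a [treatment_summary] to a single tidy CSV with a `record`
#' column: `"score"` rows hold one per-neuron windowed maximum-response score
#' per row, `"trace"` rows hold the per-treatment mean +/- SEM trace, one time
#' point per row. Column order is fixed, so identical summaries produce
#' byte-identical files. Scores round-trip at full double precision.
#'
#' @param summaries A [treatment_summary] (from [summarize_treatment()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_summary_table()]
#' @export
write_summary_table <- function(summaries, path) {
  if (!inherits(summaries, "treatment_summary")) {
    stop_validation("`summaries` must be a treatment_summary object")
  }
  if (nrow(summaries$scores) == 0L) {
    stop_validation("treatment summary is empty: nothing to write")
  }
  score_rows <- tibble::tibble(
    record = "score",
    treatment = summaries$scores$treatment,
    brain_id = as.character(summaries$scores$brain_id),
    roi_id = as.character(summaries$scores$roi_id),
    t = NA_real_,
    mean = NA_real_,
    sem = NA_real_,
    n = NA_integer_,
    baseline_mean = summaries$scores$baseline_mean,
    max_long = summaries$scores$max_long,
    max_short = summaries$scores$max_short
  )
  trace_rows <- tibble::tibble(
    record = "trace",
    treatment = summaries$traces$treatment,
    brain_id = NA_character_,
    roi_id = NA_character_,
    t = summaries$traces$t,
    mean = summaries$traces$mean,
    sem = summaries$traces$sem,
    n = summaries$traces$n,
    baseline_mean = NA_real_,
    max_long = NA_real_,
    max_short = NA_real_
  )
  out <- dplyr::bind_rows(score_rows, trace_rows)
  out <- dplyr::arrange(out, .data$record, .data$treatment, .data$brain_id,
                        .data$roi_id, .data$t)
  write_csv_precise(out, path)
  invisible(path)
}

#' Read a summary table written by [write_summary_table()]
#'
#' @param path Path to the CSV file.
#' @return A [treatment_summary] object (neuron/brain counts are recomputed
#'   from the score rows).
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- read_csv_precise(
    path, character_cols = c("record", "treatment", "brain_id", "roi_id")
  )
  if (!"record" %in% names(raw)) {
    stop_validation("not a summary table: missing `record` column")
  }
  scores <- dplyr::select(
    dplyr::filter(raw, .data$record == "score"),
    "treatment", "brain_id", "roi_id", "baseline_mean", "max_long", "max_short"
  )
  traces <- dplyr::select(
    dplyr::filter(raw, .data$record == "trace"),
    "treatment", "t", "mean", "sem", "n"
  )
  counts <- dplyr::summarise(
    dplyr::group_by(scores, .data$treatment),
    n_neurons = dplyr::n(),
    n_brains = length(unique(.data$brain_id)),
    .groups = "drop"
  )
  new_treatment_summary(traces = traces, scores = scores, counts = counts)
}
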