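#' Load a run configuration
#'
#' A run configuration is a plain named list (typically from a YAML file)
#' that fixes everything a pipeline run needs: input (a trace/count CSV or a
#' simulation spec), analysis windows, spillover fraction, statistical
#' options (comparison family, bootstrap size, alpha tiers), the RNG seed and
#' the output directory. The seed is recorded in every manifest.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param config A named list of configuration entries.
#' @param dir Base directory against which relative input paths are resolved.
#' @export
as_run_config <- function(config, dir = ".") {
  if (inherits(config, "run_config")) return(config)
  if (!is.list(config)) stop_validation("config must be a named list")
  defaults <- list(
    mode = "fret",
    input = NULL,
    spec = NULL,
    application_time = 100,
    frame_rate = 0.2,
    windows = list(baseline = c(0, 100), long = c(100, 1000),
                   short = c(100, 200)),
    spillover_k = 0.357,
    eps = 1e-9,
    invalid_frame_fraction_max = 0.1,
    family = NULL,
    synergy = NULL,
    two_factor = FALSE,
    n_boot = 2000,
    seed = 1L,
    out_dir = "ipcquant_out",
    plots = TRUE
  )
  cfg <- utils::modifyList(defaults, config)
  for (f in c("input", "spec")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      candidate <- file.path(dir, cfg[[f]])
      if (file.exists(candidate)) cfg[[f]] <- candidate
    }
  }
  if (!cfg$mode %in% c("fret", "calcium")) {
    stop_validation("config `mode` must be \"fret\" or \"calcium\"")
  }
  cfg$windows <- do.call(analysis_windows, lapply(cfg$windows, as.numeric))
  structure(cfg, class = "run_config")
}

config_inputs_exist <- function(config) {
  for (f in c("input", "spec")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop_validation(sprintf("configured %s file does not exist: %s",
                              f, config[[f]]))
    }
  }
  invisible(TRUE)
}

write_manifest <- function(out_dir, config, files, seed) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "ipcquant",
    version = as.character(utils::packageVersion("ipcquant")),
    seed = seed,
    config = config_for_manifest(config),
    outputs = lapply(setNames(nm = basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$windows <- unclass(cfg$windows)
  cfg
}

save_plot <- function(plot, path) {
  tryCatch({
    suppressMessages(ggplot2::ggsave(path, plot, width = 7, height = 4.5,
                                     dpi = 150))
    path
  }, error = function(e) {
    warn(sprintf("plotting skipped (%s)", conditionMessage(e)))
    NULL
  })
}

#' Run the live-imaging quantification pipeline end to end
#'
#' Loads (or simulates) an ROI trace set, quantifies per-neuron normalized
#' responses (inverse FRET for `mode = "fret"`, dF/F0 for `mode =
#' "calcium"`), summarizes per treatment, runs the omnibus and
#' Bonferroni-corrected pairwise comparisons on both scoring windows, and —
#' when the config names a `synergy` triple — the bootstrap synergy excess.
#' All tables are written as CSV/JSON to `out_dir` together with a manifest
#' recording the configuration, seed, package version and an MD5 digest of
#' every output file. Given identical inputs, config and seed, all numeric
#' outputs are byte-identical across runs.
#'
#' @param config A `run_config`, a named list coercible to one, or a path to
#'   a YAML config file. Keys: `mode`, `input` (trace CSV) or `spec`
#'   (simulation spec YAML), `application_time`, `frame_rate`, `windows`,
#'   `spillover_k`, `eps`, `invalid_frame_fraction_max`, `family` (list of
#'   treatment pairs; default all pairs), `synergy` (list with `combined`,
#'   `single_a`, `single_b`, optional `window`), `n_boot`, `seed`, `out_dir`,
#'   `plots`.
#' @return Invisibly, a list with the trace set, responses, summary,
#'   comparisons, synergy result (or NULL) and the output file paths.
#' @export
run_fret_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- as_run_config(config)
  config_inputs_exist(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$input)) {
    traces <- read_trace_table(config$input,
                               application_time = config$application_time,
                               frame_rate = config$frame_rate)
  } else if (!is.null(config$spec)) {
    spec <- read_simulation_spec(config$spec)
    spec$seed <- as.integer(config$seed)
    traces <- if (config$mode == "fret") simulate_fret_experiment(spec)
              else simulate_calcium_experiment(spec)
  } else {
    stop_validation("config must provide either `input` or `spec`")
  }

  responses <- if (config$mode == "fret") {
    quantify_fret(traces, windows = config$windows, k = config$spillover_k,
                  eps = config$eps,
                  max_invalid_frac = config$invalid_frame_fraction_max)
  } else {
    quantify_calcium(traces, windows = config$windows, eps = config$eps)
  }
  summary <- summarize_treatment(responses)

  comparisons <- list()
  for (w in c("long", "short")) {
    groups <- score_vectors(summary, w)
    comparisons[[w]] <- if (length(groups) >= 2L &&
                            all(lengths(groups) >= 3L)) {
      compare_treatments(groups, family = config$family)
    } else NULL
  }

  synergy <- NULL
  if (!is.null(config$synergy)) {
    sw <- config$synergy$window %||% "short"
    groups <- score_vectors(summary, sw)
    need <- c(config$synergy$combined, config$synergy$single_a,
              config$synergy$single_b)
    missing_groups <- setdiff(need, names(groups))
    if (length(missing_groups) > 0L) {
      stop_validation(sprintf("synergy treatment(s) absent from data: %s",
                              paste(missing_groups, collapse = ", ")))
    }
    synergy <- synergy_excess(groups[[need[1]]], groups[[need[2]]],
                              groups[[need[3]]], n_boot = config$n_boot,
                              seed = config$seed)
  }

  files <- character(0)
  p <- file.path(out_dir, "normalized_traces.csv")
  write_csv_precise(responses$traces, p); files <- c(files, p)
  p <- file.path(out_dir, "summary.csv")
  write_summary_table(summary, p); files <- c(files, p)
  p <- file.path(out_dir, "rejected_rois.csv")
  write_csv_precise(responses$rejected, p); files <- c(files, p)
  for (w in names(comparisons)) {
    if (is.null(comparisons[[w]])) next
    p <- file.path(out_dir, sprintf("comparison_%s.csv", w))
    out <- comparisons[[w]]$pairwise
    out$omnibus_H <- comparisons[[w]]$omnibus$statistic
    out$omnibus_p <- comparisons[[w]]$omnibus$p_value
    write_csv_precise(out, p); files <- c(files, p)
  }
  if (!is.null(synergy)) {
    p <- file.path(out_dir, "synergy.json")
    jsonlite::write_json(
      list(excess = synergy$excess, ci = synergy$ci,
           p_value = synergy$p_value, center = synergy$center,
           n = as.list(synergy$n), n_boot = synergy$n_boot,
           seed = synergy$seed),
      p, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, p)
  }
  if (isTRUE(config$plots)) {
    f <- save_plot(plot_treatment_traces(summary, config$application_time),
                   file.path(out_dir, "traces_mean_sem.png"))
    files <- c(files, f)
    f <- save_plot(plot_max_response(summary, "long"),
                   file.path(out_dir, "max_response_long.png"))
    files <- c(files, f)
    f <- save_plot(plot_max_response(summary, "short"),
                   file.path(out_dir, "max_response_short.png"))
    files <- c(files, f)
  }
  manifest <- write_manifest(out_dir, config, files, seed = config$seed)

  invisible(list(traces = traces, responses = responses, summary = summary,
                 comparisons = comparisons, synergy = synergy,
                 files = c(files, manifest)))
}

#' Run the dormancy analysis pipeline end to end
#'
#' Loads (or simulates) a replicate-level dormancy count table, computes
#' per-replicate proportions, fits the arcsine-transform ANOVA (one-way
#' across genotypes, or the genotype x photoperiod factorial when
#' `two_factor` is set) with Tukey HSD contrasts, and writes tables, a bar
#' plot on the percent scale, and a manifest.
#'
#' @param config A `run_config`-style list or YAML path. Keys used: `input`
#'   (dormancy CSV) or `dormancy_sim` (list with `genotype_probs`, optional
#'   `photoperiod_effects`, `n_replicates`, `n_per_replicate`), `two_factor`,
#'   `seed`, `out_dir`, `plots`.
#' @return Invisibly, a list with the table, the `dormancy_analysis` and the
#'   output paths.
#' @export
run_dormancy_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- as_run_config(config)
  config_inputs_exist(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$input)) {
    table <- read_dormancy_table(config$input)
  } else if (!is.null(config$dormancy_sim)) {
    sim <- config$dormancy_sim
    if (is.null(sim$genotype_probs)) {
      stop_validation("dormancy_sim needs `genotype_probs`")
    }
    table <- simulate_dormancy_counts(
      genotype_probs = unlist(sim$genotype_probs),
      photoperiod_effects = if (!is.null(sim$photoperiod_effects))
        unlist(sim$photoperiod_effects) else NULL,
      n_replicates = sim$n_replicates %||% 5,
      n_per_replicate = sim$n_per_replicate %||% 60,
      seed = config$seed
    )
  } else {
    stop_validation("config must provide either `input` or `dormancy_sim`")
  }

  analysis <- if (isTRUE(config$two_factor)) anova_twofactor(table)
              else anova_oneway_tukey(table)

  files <- character(0)
  p <- file.path(out_dir, "dormancy_replicates.csv")
  write_csv_precise(analysis$proportions$replicates, p)
  files <- c(files, p)
  p <- file.path(out_dir, "dormancy_groups.csv")
  write_csv_precise(analysis$proportions$groups, p)
  files <- c(files, p)
  p <- file.path(out_dir, "dormancy_anova.csv")
  write_csv_precise(analysis$anova, p)
  files <- c(files, p)
  tukey <- analysis$tukey
  if (is.data.frame(tukey)) tukey <- list(genotype = tukey)
  for (nm in names(tukey)) {
    p <- file.path(out_dir, sprintf("dormancy_tukey_%s.csv", nm))
    write_csv_precise(tukey[[nm]], p)
    files <- c(files, p)
  }
  if (isTRUE(config$plots)) {
    f <- save_plot(plot_dormancy(analysis),
                   file.path(out_dir, "dormancy_bars.png"))
    files <- c(files, f)
  }
  manifest <- write_manifest(out_dir, config, files, seed = config$seed)
  invisible(list(table = table, analysis = analysis,
                 files = c(files, manifest)))
}
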