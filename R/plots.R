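#' Mean +/- SEM trace plot per treatment
#'
#' Average normalized response traces with an SEM ribbon, one color per
#' treatment — the standard panel layout for bath-application experiments
#' (application point marked by a vertical line).
#'
#' @param summary A [treatment_summary].
#' @param application_time Application time in seconds (vertical mark).
#' @return A ggplot object.
#' @export
plot_treatment_traces <- function(summary, application_time = 100) {
  df <- summary$traces
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mean,
                                   color = .data$treatment,
                                   fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = application_time, linetype = "dashed",
                        color = "grey30") +
    ggplot2::labs(x = "time (s)", y = "normalized response (% change)") +
    ggplot2::theme_classic()
}

#' Maximum-response bar plot with neuron counts
#'
#' Mean +/- SEM of per-neuron windowed maximum responses per treatment, with
#' the neuron count printed in parentheses under each bar.
#'
#' @param summary A [treatment_summary].
#' @param window `"long"` or `"short"`.
#' @return A ggplot object.
#' @export
plot_max_response <- function(summary, window = c("long", "short")) {
  window <- match.arg(window)
  scores <- score_vectors(summary, window)
  df <- tibble::tibble(
    treatment = names(scores),
    mean = vapply(scores, mean, numeric(1)),
    sem = vapply(scores, sem, numeric(1)),
    n = vapply(scores, length, integer(1))
  )
  df$label <- sprintf("%s\n(%d)", df$treatment, df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean,
                                   fill = .data$treatment)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::labs(x = NULL,
                  y = sprintf("max response, %s window (%% change)", window)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_classic()
}

#' Dormancy bar plot on the percent scale
#'
#' Group mean +/- SEM of the replicate dormancy proportions, displayed as
#' percentages (inference happens on the arcsine scale; display stays
#' untransformed).
#'
#' @param proportions A `dormancy_proportions` object (or a
#'   `dormancy_analysis`, whose proportions are used).
#' @return A ggplot object.
#' @export
plot_dormancy <- function(proportions) {
  if (inherits(proportions, "dormancy_analysis")) {
    proportions <- proportions$proportions
  }
  df <- proportions$groups
  has_pp <- "photoperiod" %in% names(df)
  aes <- if (has_pp) {
    ggplot2::aes(x = .data$genotype, y = 100 * .data$mean_proportion,
                 fill = .data$photoperiod)
  } else {
    ggplot2::aes(x = .data$genotype, y = 100 * .data$mean_proportion,
                 fill = .data$genotype)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$mean_proportion - .data$sem_proportion),
                   ymax = 100 * (.data$mean_proportion + .data$sem_proportion)),
      width = 0.25, position = ggplot2::position_dodge(width = 0.9)
    ) +
    ggplot2::labs(x = NULL, y = "females with ovarian arrest (%)") +
    ggplot2::theme_classic()
  if (!has_pp) p <- p + ggplot2::guides(fill = "none")
  p
}
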