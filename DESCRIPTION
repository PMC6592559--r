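Package: ipcquant
Title: Quantification of Neuropeptide-Evoked cAMP and Calcium Responses and
    Reproductive Dormancy Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for live-imaging pharmacology of insect
    insulin-producing cells and for reproductive dormancy assays. Converts
    raw two-channel Epac1-camps FRET traces into background- and
    spillover-corrected inverse FRET (cAMP) responses, and single-channel
    GCaMP traces into dF/F0 (calcium) responses, normalized to the
    pre-application baseline and scored as windowed per-neuron maximum
    responses. Provides the accompanying statistics (Shapiro-Wilk gated test
    selection, Kruskal-Wallis with Bonferroni-corrected pairwise Wilcoxon
    tests, a bootstrap synergy-excess score for peptide co-application,
    arcsine-transform ANOVA with Tukey HSD for replicate-level dormancy
    proportions, and 2^-ddCt expression ratios), plus a forward simulator of
    dual-channel sensor traces and binomial dormancy counts so that every
    pipeline stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
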