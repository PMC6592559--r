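#' Demonstration simulation spec for the cAMP (FRET) experiment panel
#'
#' Treatment classes named after the standard bath-application panel —
#' vehicle saline (HL3), adenylate cyclase activator positive control
#' (NKH477), single peptides with and without TTX, co-application at full and
#' half dose, and co-application in TTX. Peak amplitudes are placed near the
#' approximate percent responses such experiments report (single peptides
#' ~10%, co-application ~15% with a fast ~8% transient in the 100-200 s
#' window, ~13% in TTX with the fast transient blocked, a post-400 s decline
#' at half dose) — for demonstration and pipeline testing only; they are not
#' measurements.
#'
#' @param seed Integer RNG seed.
#' @param n_brains,neurons_per_brain Per-treatment layout (default 5 x 4 =
#'   20 neurons).
#' @param ... Passed on to [simulation_spec()] to override acquisition/sensor
#'   defaults.
#' @return A [simulation_spec].
#' @export
fret_demo_spec <- function(seed, n_brains = 5, neurons_per_brain = 4, ...) {
  gain <- list(...)$gain %||% 0.05
  a <- function(pct) latent_amplitude_for_peak(pct, gain = gain)
  slow <- function(pct, ...) {
    list(kinetics = response_kinetics(a_slow = a(pct), tau_slow = 200, ...),
         role = "experimental")
  }
  treatments <- list(
    HL3 = list(kinetics = response_kinetics(), role = "negative_control"),
    NKH477 = list(kinetics = response_kinetics(a_slow = a(25), tau_slow = 150),
                  role = "positive_control"),
    PDF = slow(10),
    PDF_TTX = slow(10),
    sNPF = slow(10),
    sNPF_TTX = slow(10),
    sNPF_PDF = list(
      kinetics = response_kinetics(a_slow = a(15), tau_slow = 200,
                                   a_fast = a(6.7), tau_fast_rise = 10,
                                   tau_fast_decay = 40),
      role = "experimental"
    ),
    sNPF_PDF_half = list(
      kinetics = response_kinetics(a_slow = a(10), tau_slow = 200,
                                   a_fast = a(4), tau_fast_rise = 10,
                                   tau_fast_decay = 40,
                                   t_decline = 400, tau_decline = 600),
      role = "experimental"
    ),
    sNPF_PDF_TTX = list(
      kinetics = response_kinetics(a_slow = a(13), tau_slow = 200,
                                   a_fast = a(6.7), tau_fast_rise = 10,
                                   tau_fast_decay = 40,
                                   ttx_blocks_fast = TRUE),
      role = "experimental"
    )
  )
  simulation_spec(treatments = treatments, n_brains = n_brains,
                  neurons_per_brain = neurons_per_brain, seed = seed, ...)
}

#' Demonstration simulation spec for the calcium (GCaMP) experiment panel
#'
#' Vehicle saline, carbamylcholine positive control (robust ~30% transient),
#' PDF (no calcium response), and sNPF with and without TTX (small fast
#' transients peaking near 3.4% and 5.4% dF/F0 inside the 100-200 s scoring
#' window). Demonstration amplitudes only.
#'
#' @inheritParams fret_demo_spec
#' @return A [simulation_spec].
#' @export
calcium_demo_spec <- function(seed, n_brains = 5, neurons_per_brain = 4, ...) {
  fast <- function(amp, role = "experimental", rise = 20, decay = 100) {
    list(kinetics = response_kinetics(a_fast = amp, tau_fast_rise = rise,
                                      tau_fast_decay = decay),
         role = role)
  }
  treatments <- list(
    HL3 = list(kinetics = response_kinetics(), role = "negative_control"),
    CCh = fast(0.30, role = "positive_control", rise = 5, decay = 200),
    PDF = list(kinetics = response_kinetics(), role = "experimental"),
    sNPF = fast(0.034),
    sNPF_TTX = fast(0.054)
  )
  simulation_spec(treatments = treatments, n_brains = n_brains,
                  neurons_per_brain = neurons_per_brain, seed = seed, ...)
}

#' All-null simulation spec
#'
#' Every treatment class has zero latent amplitude, so any detected
#' differences are false positives — used for type-I error calibration.
#'
#' @param seed Integer RNG seed.
#' @param treatments Character vector of treatment labels (first is the
#'   negative control).
#' @inheritParams fret_demo_spec
#' @return A [simulation_spec].
#' @export
null_fret_spec <- function(seed, treatments = c("HL3", "A", "B", "C"),
                           n_brains = 5, neurons_per_brain = 4, ...) {
  trts <- lapply(seq_along(treatments), function(i) {
    list(kinetics = response_kinetics(),
         role = if (i == 1L) "negative_control" else "experimental")
  })
  names(trts) <- treatments
  simulation_spec(treatments = trts, n_brains = n_brains,
                  neurons_per_brain = neurons_per_brain, seed = seed, ...)
}

#' Write a simulation spec to a YAML file
#'
#' @param spec A [simulation_spec].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_spec <- function(spec, path) {
  if (!inherits(spec, "simulation_spec")) {
    stop_validation("`spec` must be a simulation_spec")
  }
  out <- unclass(spec)
  out$treatments <- lapply(out$treatments, function(tr) {
    list(role = tr$role, kinetics = unclass(tr$kinetics))
  })
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Read a simulation spec from a YAML file
#'
#' @param path Path to a YAML file written by [write_simulation_spec()] (or
#'   hand-authored with the same keys).
#' @return A [simulation_spec].
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$treatments)) stop_validation("spec file has no `treatments`")
  treatments <- lapply(raw$treatments, function(tr) {
    kin <- tr$kinetics %||% list()
    kin <- lapply(kin, function(v) if (identical(v, ".inf")) Inf else v)
    list(kinetics = do.call(response_kinetics, kin),
         role = tr$role %||% "experimental")
  })
  args <- raw[setdiff(names(raw), "treatments")]
  args$treatments <- treatments
  do.call(simulation_spec, args)
}
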