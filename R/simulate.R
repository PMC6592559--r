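#' Latent response kinetics for one treatment class
#'
#' Phenomenological model of the latent second-messenger signal c(t) driving
#' the sensor: zero before bath application, then the sum of a saturating
#' slow rise and a fast alpha-function transient, optionally multiplied by a
#' delayed exponential decline. The model is invented to reproduce the
#' qualitative trace shapes seen in bath-application experiments (slow cAMP
#' rise to single peptides, a rapid extra transient on co-application, a
#' post-400 s decline at half dose); no quantitative kinetics are claimed.
#'
#' @param t_app Application time (s).
#' @param a_slow Peak latent amplitude of the slow saturating component
#'   (fraction of baseline signal, >= 0).
#' @param tau_slow Time constant of the slow rise (s, > 0).
#' @param a_fast Amplitude of the fast transient (unit-peak alpha function).
#' @param tau_fast_rise,tau_fast_decay Rise and decay time constants of the
#'   fast transient (s, rise < decay).
#' @param t_decline Optional onset time (s) of a late decline; `Inf` (default)
#'   disables it.
#' @param tau_decline Time constant of the late decline (s).
#' @param ttx_blocks_fast Logical: when `TRUE` the fast transient is removed,
#'   modeling TTX block of the action-potential-dependent (indirect)
#'   component while the direct slow component persists.
#' @return A list of class `response_kinetics`.
#' @export
response_kinetics <- function(t_app = 100, a_slow = 0, tau_slow = 200,
                              a_fast = 0, tau_fast_rise = 10,
                              tau_fast_decay = 40, t_decline = Inf,
                              tau_decline = 300, ttx_blocks_fast = FALSE) {
  assert_number(t_app, "t_app", lower = 0)
  for (nm in c("a_slow", "a_fast")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_validation(sprintf("`%s` must be a single number >= 0", nm))
    }
  }
  for (nm in c("tau_slow", "tau_fast_rise", "tau_fast_decay", "tau_decline")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_validation(sprintf("`%s` must be a single number > 0", nm))
    }
  }
  if (tau_fast_rise >= tau_fast_decay) {
    stop_validation("`tau_fast_rise` must be smaller than `tau_fast_decay`")
  }
  if (!(is.numeric(t_decline) && length(t_decline) == 1L &&
        (is.infinite(t_decline) || t_decline >= 0))) {
    stop_validation("`t_decline` must be >= 0 or Inf")
  }
  structure(
    list(t_app = t_app, a_slow = a_slow, tau_slow = tau_slow, a_fast = a_fast,
         tau_fast_rise = tau_fast_rise, tau_fast_decay = tau_fast_decay,
         t_decline = t_decline, tau_decline = tau_decline,
         ttx_blocks_fast = isTRUE(ttx_blocks_fast)),
    class = "response_kinetics"
  )
}

#' Evaluate the latent signal c(t)
#'
#' @param kinetics A [response_kinetics] object.
#' @param t Numeric vector of times (s).
#' @return Latent amplitude c(t) (same length as `t`); 0 for `t < t_app`.
#' @export
latent_signal <- function(kinetics, t) {
  if (!inherits(kinetics, "response_kinetics")) {
    stop_validation("`kinetics` must be a response_kinetics object")
  }
  s <- t - kinetics$t_app
  c_t <- numeric(length(t))
  on <- s >= 0
  if (any(on)) {
    slow <- kinetics$a_slow * (1 - exp(-s[on] / kinetics$tau_slow))
    a_fast <- if (kinetics$ttx_blocks_fast) 0 else kinetics$a_fast
    fast <- 0
    if (a_fast > 0) {
      tr <- kinetics$tau_fast_rise; td <- kinetics$tau_fast_decay
      # normalized double exponential with unit peak
      s_peak <- log(td / tr) * tr * td / (td - tr)
      peak <- exp(-s_peak / td) - exp(-s_peak / tr)
      fast <- a_fast * (exp(-s[on] / td) - exp(-s[on] / tr)) / peak
    }
    c_t[on] <- slow + fast
  }
  if (is.finite(kinetics$t_decline)) {
    late <- t > kinetics$t_decline
    c_t[late] <- c_t[late] *
      exp(-(t[late] - kinetics$t_decline) / kinetics$tau_decline)
  }
  c_t
}

#' Latent amplitude needed for a target peak iFRET response
#'
#' With the ratiometric sensor model used by [simulate_fret_experiment()]
#' (`CFP = C0 (1 + g c)`, spillover-free `YFP = Y0 (1 - g c)`), the
#' baseline-normalized iFRET percent change at latent amplitude `c` is
#' `((1 + g c) / (1 - g c) - 1) * 100`, independent of `C0`, `Y0` and the
#' spillover fraction (which the analysis removes exactly). This inverts that
#' map so simulations can inject an exact peak percent response.
#'
#' @param percent Target peak normalized response (% change, > -100).
#' @param gain Sensor gain `g` (fractional channel change per unit latent
#'   signal).
#' @return Latent amplitude `c` whose peak produces `percent`.
#' @seealso [ifret_percent_from_latent()]
#' @export
latent_amplitude_for_peak <- function(percent, gain = 0.05) {
  assert_number(gain, "gain", lower = 1e-12)
  r <- 1 + percent / 100
  if (any(r <= 0)) stop_validation("percent must exceed -100")
  ((r - 1) / (r + 1)) / gain
}

#' Normalized iFRET percent change produced by a latent amplitude
#'
#' Closed-form forward map of the simulator's sensor model; inverse of
#' [latent_amplitude_for_peak()].
#'
#' @param c_latent Latent amplitude(s).
#' @param gain Sensor gain `g`.
#' @return Percent change of baseline-normalized iFRET.
#' @export
ifret_percent_from_latent <- function(c_latent, gain = 0.05) {
  x <- gain * c_latent
  if (any(x >= 1)) stop_validation("gain * c must stay below 1")
  ((1 + x) / (1 - x) - 1) * 100
}

#' Full parameterization of a synthetic imaging experiment
#'
#' Bundles the treatment classes (each a [response_kinetics] plus a role)
#' with the acquisition and sensor parameters. Defaults mirror the standard
#' protocol (0.2 Hz for 1000 s, application at 100 s) and plausible bright
#' CCD ROI statistics; every parameter is explicit so simulations are fully
#' reproducible from the spec alone.
#'
#' @param treatments Named list; each element a list with `kinetics`
#'   (a [response_kinetics]) and `role` (see [treatment_design()]).
#' @param n_brains Brains per treatment.
#' @param neurons_per_brain ROIs (cell bodies) per brain.
#' @param frame_rate Acquisition rate (Hz, default 0.2).
#' @param duration Recording length (s, default 1000).
#' @param c0,y0 Baseline CFP and YFP intensities (arbitrary units).
#' @param g0 Baseline GFP intensity for calcium simulations.
#' @param gain Sensor gain `g`: fractional CFP increase and YFP decrease per
#'   unit latent signal (rising cAMP lowers FRET, so CFP rises and YFP
#'   falls).
#' @param spillover_k CFP-into-YFP spillover fraction applied when
#'   synthesizing the measured YFP channel (default 0.357).
#' @param bg_level Background intensity (a.u.).
#' @param bg_drift Linear background drift (a.u. per second).
#' @param noise_sd_frac Gaussian noise SD per channel, as a fraction of that
#'   channel's baseline intensity (default 0.002).
#' @param bleach_tau Shared photobleaching time constant (s); `Inf` disables
#'   bleaching. Bleaching multiplies both channels and cancels in the iFRET
#'   ratio.
#' @param neuron_cv Coefficient of variation of the lognormal (mean 1)
#'   neuron-to-neuron multiplier applied to the latent amplitudes.
#' @param seed Integer RNG seed (required).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(treatments, n_brains = 5, neurons_per_brain = 4,
                            frame_rate = 0.2, duration = 1000,
                            c0 = 1000, y0 = 2000, g0 = 1000, gain = 0.05,
                            spillover_k = 0.357, bg_level = 50,
                            bg_drift = 0.02, noise_sd_frac = 0.002,
                            bleach_tau = Inf, neuron_cv = 0.1, seed) {
  if (missing(seed)) stop_validation("`seed` is required")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_validation("`seed` must be an integer")
  if (!is.list(treatments) || length(treatments) == 0L ||
      is.null(names(treatments)) || any(names(treatments) == "")) {
    stop_validation("`treatments` must be a non-empty named list")
  }
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    if (!is.list(tr) || !inherits(tr$kinetics, "response_kinetics")) {
      stop_validation(sprintf("treatment `%s` must carry a response_kinetics", nm))
    }
    treatments[[nm]]$role <- tr$role %||% "experimental"
  }
  assert_number(n_brains, "n_brains", lower = 1)
  assert_number(neurons_per_brain, "neurons_per_brain", lower = 1)
  assert_number(frame_rate, "frame_rate", lower = 1e-9)
  assert_number(duration, "duration", lower = 1)
  assert_number(c0, "c0", lower = 1e-9)
  assert_number(y0, "y0", lower = 1e-9)
  assert_number(g0, "g0", lower = 1e-9)
  assert_number(gain, "gain", lower = 0)
  assert_number(spillover_k, "spillover_k", lower = 0)
  if (spillover_k >= 1) stop_validation("`spillover_k` must be < 1")
  assert_number(bg_level, "bg_level", lower = 0)
  assert_number(bg_drift, "bg_drift", lower = -1e6)
  assert_number(noise_sd_frac, "noise_sd_frac", lower = 0)
  if (!(is.numeric(bleach_tau) && length(bleach_tau) == 1L &&
        (is.infinite(bleach_tau) || bleach_tau > 0))) {
    stop_validation("`bleach_tau` must be > 0 or Inf")
  }
  assert_number(neuron_cv, "neuron_cv", lower = 0)
  structure(
    list(treatments = treatments, n_brains = as.integer(n_brains),
         neurons_per_brain = as.integer(neurons_per_brain),
         frame_rate = frame_rate, duration = duration, c0 = c0, y0 = y0,
         g0 = g0, gain = gain, spillover_k = spillover_k,
         bg_level = bg_level, bg_drift = bg_drift,
         noise_sd_frac = noise_sd_frac, bleach_tau = bleach_tau,
         neuron_cv = neuron_cv, seed = seed),
    class = "simulation_spec"
  )
}

# Deterministic per-neuron substream: independent of iteration order, keyed
# by (seed, treatment, brain, neuron); kept inside 32-bit integer range.
neuron_subseed <- function(seed, i_trt, i_brain, i_roi) {
  as.integer((as.double(seed) + 1e6 * i_trt + 1e4 * i_brain + 97 * i_roi) %%
               2147483647)
}

sim_frame_times <- function(spec) {
  period <- 1 / spec$frame_rate
  seq(0, spec$duration - period, by = period)
}

neuron_jitter <- function(cv) {
  if (cv <= 0) return(1)
  sdlog <- sqrt(log(1 + cv^2))
  # lognormal with mean exactly 1
  exp(rnorm(1, mean = -sdlog^2 / 2, sd = sdlog))
}

sim_experiment <- function(spec, channels_fun, channel_names) {
  t <- sim_frame_times(spec)
  bleach <- if (is.infinite(spec$bleach_tau)) rep(1, length(t)) else
    exp(-t / spec$bleach_tau)
  bg <- spec$bg_level + spec$bg_drift * t
  rows <- list()
  trt_names <- names(spec$treatments)
  for (i_trt in seq_along(trt_names)) {
    trt <- trt_names[i_trt]
    kin <- spec$treatments[[trt]]$kinetics
    base_c <- latent_signal(kin, t)
    for (i_brain in seq_len(spec$n_brains)) {
      brain <- sprintf("%s_b%02d", trt, i_brain)
      for (i_roi in seq_len(spec$neurons_per_brain)) {
        set.seed(neuron_subseed(spec$seed, i_trt, i_brain, i_roi))
        jit <- neuron_jitter(spec$neuron_cv)
        c_t <- base_c * jit
        rows[[length(rows) + 1L]] <- channels_fun(
          trt, brain, sprintf("roi%02d", i_roi), t, c_t, bleach, bg
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a dual-channel FRET imaging experiment
#'
#' Forward model: per neuron, the latent signal c(t) of its treatment class
#' (amplitudes jittered by a lognormal mean-1 neuron-to-neuron multiplier)
#' drives the sensor channels
#' `CFP_true = C0 (1 + g c) b(t)` and `YFP_true = Y0 (1 - g c) b(t)`
#' (rising cAMP lowers FRET: CFP emission up, YFP emission down), with shared
#' bleaching `b(t)`. Measured channels add spillover, background and
#' Gaussian noise: `CFP = CFP_true + bg + e1`,
#' `YFP = YFP_true + k CFP_true + bg + e2`. The emitted table carries the
#' background as `bg_cfp`/`bg_yfp` columns, so the analysis chain can undo it
#' exactly. Fully reproducible per seed (per-neuron substreams are derived
#' from the seed and neuron identity, not from iteration order).
#'
#' @param spec A [simulation_spec].
#' @return An [roi_trace_set] with `cfp`, `yfp`, `bg_cfp`, `bg_yfp` columns.
#' @export
simulate_fret_experiment <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop_validation("`spec` must be a simulation_spec")
  }
  t_app <- spec$treatments[[1]]$kinetics$t_app
  data <- sim_experiment(spec, function(trt, brain, roi, t, c_t, bleach, bg) {
    if (any(spec$gain * c_t >= 1)) {
      stop_validation("gain * latent signal reached 1: YFP would go negative")
    }
    cfp_true <- spec$c0 * (1 + spec$gain * c_t) * bleach
    yfp_true <- spec$y0 * (1 - spec$gain * c_t) * bleach
    n <- length(t)
    cfp <- cfp_true + bg + rnorm(n, sd = spec$noise_sd_frac * spec$c0)
    yfp <- yfp_true + spec$spillover_k * cfp_true + bg +
      rnorm(n, sd = spec$noise_sd_frac * spec$y0)
    tibble::tibble(
      brain_id = brain, roi_id = roi, treatment = trt, t = t,
      cfp = pmax(cfp, 0), yfp = pmax(yfp, 0), bg_cfp = bg, bg_yfp = bg
    )
  })
  roi_trace_set(data, application_time = t_app, frame_rate = spec$frame_rate)
}

#' Simulate a single-channel calcium imaging experiment
#'
#' `GFP = G0 (1 + c(t)) b(t) + bg + noise`: the latent amplitude is the
#' fractional fluorescence change itself, so a noiseless peak `c = 0.034`
#' yields a pipeline dF/F0 maximum of exactly 3.4%.
#'
#' @param spec A [simulation_spec].
#' @return An [roi_trace_set] with `gfp` and `bg_gfp` columns.
#' @export
simulate_calcium_experiment <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop_validation("`spec` must be a simulation_spec")
  }
  t_app <- spec$treatments[[1]]$kinetics$t_app
  data <- sim_experiment(spec, function(trt, brain, roi, t, c_t, bleach, bg) {
    gfp_true <- spec$g0 * (1 + c_t) * bleach
    gfp <- gfp_true + bg + rnorm(length(t), sd = spec$noise_sd_frac * spec$g0)
    tibble::tibble(
      brain_id = brain, roi_id = roi, treatment = trt, t = t,
      gfp = pmax(gfp, 0), bg_gfp = bg
    )
  })
  roi_trace_set(data, application_time = t_app, frame_rate = spec$frame_rate)
}

#' Simulate a replicate-level dormancy count table
#'
#' Draws `n_arrested ~ Binomial(n_per_replicate, p)` per replicate vial.
#' When photoperiod effects are supplied, genotype baseline probabilities and
#' photoperiod shifts combine additively on the logit scale; probabilities of
#' exactly 0 or 1 cannot be shifted on that scale and are clamped just inside
#' (0, 1) with a warning.
#'
#' @param genotype_probs Named numeric vector: arrest probability per
#'   genotype.
#' @param photoperiod_effects Optional named numeric vector of logit-scale
#'   shifts, one per photoperiod level; when given, the design is the full
#'   genotype x photoperiod cross.
#' @param n_replicates Replicate vials per design cell (default 5).
#' @param n_per_replicate Dissected females per vial (default 60).
#' @param seed Integer RNG seed (required).
#' @return A [dormancy_table].
#' @export
simulate_dormancy_counts <- function(genotype_probs, photoperiod_effects = NULL,
                                     n_replicates = 5, n_per_replicate = 60,
                                     seed) {
  if (missing(seed)) stop_validation("`seed` is required")
  if (!is.numeric(genotype_probs) || is.null(names(genotype_probs)) ||
      any(!is.finite(genotype_probs))) {
    stop_validation("`genotype_probs` must be a named numeric vector")
  }
  if (any(genotype_probs < 0 | genotype_probs > 1)) {
    stop_validation("genotype probabilities must lie in [0, 1]")
  }
  assert_number(n_replicates, "n_replicates", lower = 1)
  assert_number(n_per_replicate, "n_per_replicate", lower = 1)
  set.seed(as.integer(seed))
  if (is.null(photoperiod_effects)) {
    design <- tibble::tibble(genotype = names(genotype_probs),
                             p = unname(genotype_probs))
  } else {
    if (!is.numeric(photoperiod_effects) || is.null(names(photoperiod_effects))) {
      stop_validation("`photoperiod_effects` must be a named numeric vector")
    }
    design <- tidyr::expand_grid(
      genotype = names(genotype_probs),
      photoperiod = names(photoperiod_effects)
    )
    p_g <- genotype_probs[design$genotype]
    boundary <- p_g <= 0 | p_g >= 1
    if (any(boundary & photoperiod_effects[design$photoperiod] != 0)) {
      warn("boundary probabilities clamped inside (0, 1) before logit shift")
    }
    p_g <- pmin(pmax(p_g, 1e-12), 1 - 1e-12)
    design$p <- plogis(qlogis(p_g) + photoperiod_effects[design$photoperiod])
  }
  rows <- design[rep(seq_len(nrow(design)), each = n_replicates), ]
  rows$replicate <- sprintf("rep%02d", rep(seq_len(n_replicates), nrow(design)))
  rows$n_dissected <- as.integer(n_per_replicate)
  rows$n_arrested <- rbinom(nrow(rows), size = as.integer(n_per_replicate),
                            prob = rows$p)
  rows$p <- NULL
  dormancy_table(rows)
}
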