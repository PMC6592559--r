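noiseless_spec <- function(treatments, seed = 1, ...) {
  simulation_spec(treatments = treatments, n_brains = 1, neurons_per_brain = 1,
                  noise_sd_frac = 0, neuron_cv = 0, bg_drift = 0,
                  seed = seed, ...)
}

test_that("latent signal obeys causality, closed forms, and TTX/decline logic", {
  kin0 <- response_kinetics()
  expect_equal(latent_signal(kin0, seq(0, 1000, by = 50)),
               rep(0, 21))

  kin <- response_kinetics(a_slow = 0.10, tau_slow = 200)
  expect_equal(latent_signal(kin, c(0, 50, 99.9)), c(0, 0, 0))
  expect_equal(latent_signal(kin, 300), 0.10 * (1 - exp(-1)))
  expect_equal(latent_signal(kin, 300), 0.06321, tolerance = 1e-4)

  # fast transient has unit peak at its analytic peak time
  kinf <- response_kinetics(a_fast = 0.08, tau_fast_rise = 10,
                            tau_fast_decay = 40)
  s_peak <- log(4) * 10 * 40 / 30
  expect_equal(latent_signal(kinf, 100 + s_peak), 0.08, tolerance = 1e-12)
  expect_lt(max(latent_signal(kinf, seq(100, 1000, by = 0.5))), 0.08 + 1e-9)

  # the TTX flag removes exactly the fast component
  kin_ttx <- response_kinetics(a_slow = 0.05, a_fast = 0.08,
                               ttx_blocks_fast = TRUE)
  kin_slow_only <- response_kinetics(a_slow = 0.05)
  t <- seq(0, 1000, by = 5)
  expect_equal(latent_signal(kin_ttx, t), latent_signal(kin_slow_only, t))

  # delayed decline multiplies the signal after t_decline only
  kin_dec <- response_kinetics(a_slow = 0.10, t_decline = 400,
                               tau_decline = 300)
  base <- response_kinetics(a_slow = 0.10)
  expect_equal(latent_signal(kin_dec, 400), latent_signal(base, 400))
  expect_equal(latent_signal(kin_dec, 700),
               latent_signal(base, 700) * exp(-1))

  expect_error(response_kinetics(tau_slow = -1), "> 0",
               class = "ipcquant_validation_error")
  expect_error(response_kinetics(a_slow = -0.1), ">= 0",
               class = "ipcquant_validation_error")
})

test_that("latent amplitude <-> percent response maps invert each other", {
  for (pct in c(0, 5, 10, 15, 25)) {
    a <- latent_amplitude_for_peak(pct, gain = 0.05)
    expect_equal(ifret_percent_from_latent(a, gain = 0.05), pct,
                 tolerance = 1e-12)
  }
  expect_equal(latent_amplitude_for_peak(0), 0)
})

test_that("simulated FRET experiments are deterministic and null under zero gain", {
  trts <- list(
    HL3 = list(kinetics = response_kinetics(), role = "negative_control"),
    PDF = list(kinetics = response_kinetics(a_slow = 0.06), role = "experimental")
  )
  spec <- simulation_spec(treatments = trts, n_brains = 2,
                          neurons_per_brain = 2, seed = 77)
  a <- simulate_fret_experiment(spec)
  b <- simulate_fret_experiment(spec)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  spec2 <- spec; spec2$seed <- 78L
  c2 <- simulate_fret_experiment(spec2)
  expect_false(identical(a$cfp, c2$cfp))

  # zero gain, zero noise: the analysis chain returns identically 0%
  null_spec <- noiseless_spec(trts, gain = 0)
  tr <- simulate_fret_experiment(null_spec)
  resp <- quantify_fret(tr)
  expect_equal(max(abs(resp$traces$value)), 0, tolerance = 1e-9)
})

test_that("noiseless single-neuron peak matches the closed-form iFRET percent", {
  trts <- list(PDF = list(kinetics = response_kinetics(a_slow = 0.05,
                                                       tau_slow = 200),
                          role = "experimental"))
  spec <- noiseless_spec(trts)
  tr <- simulate_fret_experiment(spec)
  resp <- quantify_fret(tr, k = spec$spillover_k)
  t <- sim_frame_times_for_test(spec)
  c_peak <- max(latent_signal(trts$PDF$kinetics, t[t >= 100 & t <= 1000]))
  expect_equal(resp$scores$max_long,
               ifret_percent_from_latent(c_peak, gain = spec$gain),
               tolerance = 1e-6)

  # shared bleaching cancels in the ratio
  spec_bleach <- noiseless_spec(trts, bleach_tau = 800)
  trb <- simulate_fret_experiment(spec_bleach)
  respb <- quantify_fret(trb, k = spec_bleach$spillover_k)
  expect_equal(respb$traces$value, resp$traces$value, tolerance = 1e-8)

  # analyzing with k = 0 data synthesized with k = 0.357 biases iFRET down
  resp_k0 <- quantify_fret(tr, k = 0)
  expect_lt(resp_k0$scores$max_long, resp$scores$max_long)
})

test_that("noiseless calcium peak equals the latent amplitude in percent", {
  trts <- list(sNPF = list(kinetics = response_kinetics(a_fast = 0.034,
                                                        tau_fast_rise = 20,
                                                        tau_fast_decay = 100),
                           role = "experimental"))
  spec <- noiseless_spec(trts)
  tr <- simulate_calcium_experiment(spec)
  resp <- quantify_calcium(tr)
  t <- sim_frame_times_for_test(spec)
  c_peak <- max(latent_signal(trts$sNPF$kinetics, t[t >= 100 & t <= 200]))
  expect_equal(resp$scores$max_short, 100 * c_peak, tolerance = 1e-9)
  # the sampled grid straddles the analytic peak, so the score is near 3.4
  expect_equal(resp$scores$max_short, 3.4, tolerance = 0.01)
})

test_that("dormancy count simulation hits binomial bounds and expectations", {
  t0 <- simulate_dormancy_counts(c(A = 0), n_replicates = 20, seed = 3)
  expect_true(all(t0$n_arrested == 0))
  t1 <- simulate_dormancy_counts(c(A = 1), n_replicates = 20, seed = 3)
  expect_true(all(t1$n_arrested == t1$n_dissected))

  th <- simulate_dormancy_counts(c(A = 0.5), n_replicates = 2000,
                                 n_per_replicate = 60, seed = 9)
  phat <- mean(th$n_arrested / th$n_dissected)
  se <- sqrt(0.5 * 0.5 / 60) / sqrt(2000)
  expect_lt(abs(phat - 0.5), 3 * se)

  # photoperiod effects combine on the logit scale
  tp <- simulate_dormancy_counts(c(A = 0.5), photoperiod_effects = c(LD = 0, SD = 1),
                                 n_replicates = 500, n_per_replicate = 100,
                                 seed = 11)
  props <- dormancy_proportions(tp)$groups
  expect_equal(props$mean_proportion[props$photoperiod == "SD"],
               plogis(1), tolerance = 0.02)
  expect_error(simulate_dormancy_counts(c(A = 1.5), seed = 1), "\\[0, 1\\]",
               class = "ipcquant_validation_error")
})

test_that("simulation specs round-trip through YAML", {
  spec <- fret_demo_spec(seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_spec(spec, path)
  back <- read_simulation_spec(path)
  expect_equal(names(back$treatments), names(spec$treatments))
  expect_equal(back$treatments$sNPF_PDF$kinetics, spec$treatments$sNPF_PDF$kinetics)
  expect_equal(back$seed, spec$seed)
  expect_equal(back$bleach_tau, spec$bleach_tau)
  # identical spec produces identical data
  expect_identical(
    tibble::as_tibble(simulate_fret_experiment(back)),
    tibble::as_tibble(simulate_fret_experiment(spec))
  )
})
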