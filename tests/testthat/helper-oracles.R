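# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized implementations: plain frame-by-frame loops and
# exhaustive enumerations.

# Random 20-frame toy FRET trace with guaranteed-positive channels and
# spillover denominators. Time grid 0..19 s at 1 Hz.
random_toy_trace <- function() {
  n <- 20L
  t <- as.numeric(0:(n - 1L))
  cfp_true <- runif(n, 50, 150)
  yfp_true <- runif(n, 250, 400)
  bg <- runif(n, 0, 20)
  list(
    t = t,
    cfp_raw = cfp_true + bg, yfp_raw = yfp_true + bg,
    bg = bg,
    windows = analysis_windows(baseline = c(0, 5), long = c(5, 19),
                               short = c(5, 10))
  )
}

# Frame-by-frame arithmetic evaluation of the full chain:
# background -> spillover(k) -> iFRET -> % baseline normalization -> max.
chain_oracle <- function(tr, k = 0.357) {
  n <- length(tr$t)
  ifret <- numeric(n)
  for (i in seq_len(n)) {
    cfp_i <- tr$cfp_raw[i] - tr$bg[i]
    yfp_i <- tr$yfp_raw[i] - tr$bg[i]
    denom_i <- yfp_i - k * cfp_i
    ifret[i] <- cfp_i / denom_i
  }
  base_vals <- c()
  for (i in seq_len(n)) {
    if (tr$t[i] >= tr$windows$baseline[1] && tr$t[i] < tr$windows$baseline[2]) {
      base_vals <- c(base_vals, ifret[i])
    }
  }
  b <- sum(base_vals) / length(base_vals)
  norm <- numeric(n)
  for (i in seq_len(n)) norm[i] <- (ifret[i] / b - 1) * 100
  max_in <- function(w) {
    best <- -Inf
    for (i in seq_len(n)) {
      if (tr$t[i] >= w[1] && tr$t[i] <= w[2] && norm[i] > best) best <- norm[i]
    }
    best
  }
  list(norm = norm, baseline_mean = b,
       max_long = max_in(tr$windows$long),
       max_short = max_in(tr$windows$short))
}

# Package-side evaluation of the same chain on a toy trace.
chain_pipeline <- function(tr, k = 0.357) {
  cfp <- background_correct(tr$cfp_raw, tr$bg)
  yfp <- background_correct(tr$yfp_raw, tr$bg)
  ifret <- compute_ifret(cfp, yfp, k = k)
  norm <- normalize_to_baseline(ifret, tr$t, tr$windows)
  list(
    norm = norm$values, baseline_mean = norm$baseline_mean,
    max_long = max_response(norm$values, tr$t, tr$windows$long),
    max_short = max_response(norm$values, tr$t, tr$windows$short)
  )
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled tie-free observations into groups of sizes (nA, nB) and count
# assignments whose rank-sum statistic is at least as extreme (two-sided by
# distance from its mean) as the observed one.
wilcoxon_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nA <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nA)])
  mu <- nA * (length(pooled) + 1) / 2
  idx <- utils::combn(length(pooled), nA)
  sums <- colSums(matrix(r[idx], nrow = nA))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Hand-rank Kruskal-Wallis H for tie-free data.
kw_hand_rank_H <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  stopifnot(!anyDuplicated(values))
  r <- rank(values)
  n <- length(values)
  idx <- split(seq_len(n), rep(seq_along(groups), lengths(groups)))
  s <- 0
  for (i in seq_along(groups)) {
    ri <- sum(r[idx[[i]]])
    s <- s + ri^2 / length(idx[[i]])
  }
  12 / (n * (n + 1)) * s - 3 * (n + 1)
}

# Frame grid a simulation spec produces (mirrors the simulator's definition).
sim_frame_times_for_test <- function(spec) {
  period <- 1 / spec$frame_rate
  seq(0, spec$duration - period, by = period)
}

# Tiny well-formed trace table for IO tests.
toy_trace_table <- function() {
  grid <- expand.grid(t = seq(0, 20, by = 5), roi_id = c("r1", "r2", "r3"),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    brain_id = "b1", roi_id = grid$roi_id, treatment = "PDF", t = grid$t,
    cfp = 100 + grid$t, yfp = 300 - grid$t,
    bg_cfp = 10, bg_yfp = 12
  )
}
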