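# Shared fixtures and independent brute-force oracles.

# Random censored competing-risks data, optionally with heavy ties.
make_cr_data <- function(n, seed = 1, ties = FALSE) {
  set.seed(seed)
  time <- rexp(n, 0.15) + 0.01
  if (ties) time <- round(time, 1) + 0.01
  cause <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
  list(time = time, cause = cause)
}

# Literal leave-one-out jackknife recomputation (the O(n^2) reference).
loo_pseudo_oracle <- function(time, cause, horizon, target = "cif_cause1") {
  n <- length(time)
  est <- function(tt, cc) {
    if (target == "cif_cause1") aj_cif_at(tt, cc, horizon)
    else 1 - step_eval(km_survival(tt, as.integer(cc == 1)), horizon)
  }
  full <- est(time, cause)
  vapply(seq_len(n), function(i)
    n * full - (n - 1) * est(time[-i], cause[-i]), numeric(1))
}

# Exhaustive-pair Harrell concordance with horizon truncation.
naive_harrell <- function(time, event, risk, horizon) {
  e <- as.integer(event != 0 & time <= horizon)
  tt <- pmin(time, horizon)
  num <- den <- 0
  n <- length(tt)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (e[i] == 1 && tt[i] < tt[j]) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

# Exhaustive weighted-pair IPCW concordance (literal double loop).
naive_ipcw_c <- function(time, cause, risk, horizon) {
  G <- censoring_survival(time, cause)
  gleft <- function(t) {
    idx <- findInterval(t, G$time, left.open = TRUE)
    c(1, G$estimate)[idx + 1]
  }
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (cause[i] != 1 || time[i] > horizon) next
    gi <- gleft(min(time[i], horizon))
    if (gi <= 0) next
    for (j in seq_len(n)) {
      if (j == i) next
      w <- 0
      if (time[j] > time[i]) w <- 1 / gi^2
      else if (cause[j] == 2 && time[j] <= time[i]) {
        gj <- gleft(min(time[j], horizon))
        if (gj > 0) w <- 1 / (gi * gj)
      }
      if (w > 0) {
        den <- den + w
        num <- num + w * ((risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j]))
      }
    }
  }
  num / den
}

# Clean-room Rubin's rules (Rubin 1987 arithmetic, written independently).
naive_rubin <- function(est, var) {
  m <- length(est)
  qbar <- sum(est) / m
  w <- sum(var) / m
  b <- sum((est - qbar)^2) / (m - 1)
  tt <- w + (1 + 1 / m) * b
  list(estimate = qbar, within = w, between = b, total = tt,
       df = (m - 1) * (1 + w / ((1 + 1 / m) * b))^2)
}

small_cohort <- function(n = 2500, seed = 11) {
  simulate_cohort(sim_config(n_subjects = n, seed = seed))
}
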