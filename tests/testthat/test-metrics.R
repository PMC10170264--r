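test_that("crude-rate CIs satisfy the log-symmetric identity", {
  r <- crude_rate(250, 8000)
  expect_equal(r$ci_low * r$ci_high, r$rate^2)
  expect_true(r$ci_low <= r$rate && r$rate <= r$ci_high)
  z <- crude_rate(0, 1000)
  expect_equal(z$rate, 0)
  expect_false(z$ci_defined)
  expect_error(crude_rate(10, 0), "> 0")
})

test_that("Harrell's C handles perfect ordering, ties and ordering invariance", {
  set.seed(101)
  time <- sort(rexp(50, 0.2) + 0.01)
  risk <- rev(seq_along(time)) / 50      # highest risk dies first
  expect_equal(harrells_c(time, rep(1, 50), risk, 10)$value, 1)
  expect_equal(harrells_c(time, rep(1, 50), rep(0.3, 50), 10)$value, 0.5)
  d <- make_cr_data(120, seed = 102)
  rk <- runif(120)
  a <- harrells_c(d$time, d$cause == 1, rk, 8)
  o <- sample(120)
  b <- harrells_c(d$time[o], (d$cause == 1)[o], rk[o], 8)
  expect_equal(a$value, b$value)
})

test_that("IPCW concordance equals unweighted enumeration without censoring", {
  set.seed(103)
  n <- 100
  time <- rexp(n, 0.2) + 0.01
  cause <- sample(1:2, n, TRUE, prob = c(0.7, 0.3))  # no censoring
  risk <- runif(n)
  got <- ipcw_c_index(time, cause, risk, 8)$value
  expect_equal(got, naive_ipcw_c(time, cause, risk, 8), tolerance = 1e-12)
  # perfect ordering among cases
  t2 <- sort(rexp(40, 0.3) + 0.01)
  expect_equal(ipcw_c_index(t2, rep(1, 40), rev(seq_len(40)), 10)$value, 1)
  expect_error(ipcw_c_index(rep(20, 5), rep(1, 5), runif(5), 10), "no usable")
})

test_that("calibration recovers affine transformations of the link", {
  set.seed(105)
  cfg <- sim_config(n_subjects = 20000, censor_rate = 0.02, seed = 105)
  cov <- draw_covariates(20000, cfg)
  ev <- simulate_event_times(cohort_design(cov), cfg)
  ps <- pseudo_values(ev$time, ev$cause, 10)$values
  # doubling the linear predictor of a calibrated model halves the slope
  cll <- log(-log(1 - pmin(pmax(ev$truth, 1e-6), 1 - 1e-6)))
  doubled <- 1 - exp(-exp(2 * cll))
  cal <- calibration_slope_citl(ps, doubled)
  expect_equal(cal$value[cal$metric == "slope"], 0.5, tolerance = 0.05)
  expect_error(calibration_slope_citl(ps, rep(0.2, length(ps))), "constant")
  citl_only <- calibration_citl(ps, rep(0.2, length(ps)))
  expect_true(is.finite(citl_only$value))
})

test_that("smoothed calibration curves pass the identity and flag extrapolation", {
  set.seed(107)
  r <- runif(500, 0.05, 0.6)
  cc <- smoothed_calibration_curve(r, r)
  expect_lt(max(abs(cc$observed - cc$predicted)), 1e-8)
  gg <- smoothed_calibration_curve(r, r, grid = c(0.01, 0.3, 0.9))
  expect_equal(gg$extrapolated, c(TRUE, FALSE, TRUE))
  expect_error(smoothed_calibration_curve(runif(20), runif(20)), "n >= 50")
})

test_that("decision curves obey their structural identities", {
  d <- make_cr_data(400, seed = 109)
  risk <- runif(400)
  dc <- decision_curve(d$time, d$cause, risk, horizon = 8,
                       thresholds = c(0.001, 0.1, 0.3))
  none <- dc$net_benefit[dc$strategy == "treat_none"]
  expect_equal(none, rep(0, 3))
  # threshold -> 0: treat-all net benefit -> overall event probability
  f_all <- aj_cif_at(d$time, d$cause, 8)
  ta <- dc$net_benefit[dc$strategy == "treat_all" & dc$threshold == 0.001]
  expect_equal(ta, f_all, tolerance = 1e-2)
  # empty high-risk group is flagged with zero contribution
  dc2 <- decision_curve(d$time, d$cause, rep(0.05, 400), horizon = 8,
                        thresholds = 0.5)
  expect_true(dc2$empty_group[dc2$strategy == "model"])
  expect_equal(dc2$net_benefit[dc2$strategy == "model"], 0)
})

test_that("competing-risks flag switches the event-probability estimator", {
  d <- make_cr_data(500, seed = 111)
  risk <- runif(500)
  with_cr <- decision_curve(d$time, d$cause, risk, 8, thresholds = 0.1,
                            competing = TRUE)
  without <- decision_curve(d$time, d$cause, risk, 8, thresholds = 0.1,
                            competing = FALSE)
  aj <- aj_cif_at(d$time, d$cause, 8)
  km <- 1 - step_eval(km_survival(d$time, as.integer(d$cause == 1)), 8)
  expect_equal(with_cr$net_benefit[with_cr$strategy == "treat_all"],
               aj - (1 - aj) / 9)
  expect_equal(without$net_benefit[without$strategy == "treat_all"],
               km - (1 - km) / 9)
})

test_that("subgroup metrics reduce to overall metrics and flag sparse groups", {
  d <- make_cr_data(400, seed = 113)
  tbl <- tibble::tibble(time = d$time, cause = d$cause,
                        .risk = runif(400),
                        .pseudo = pseudo_values(d$time, d$cause, 8)$values,
                        g1 = "all", g2 = rep(c("a", "b"), each = 200))
  one <- subgroup_metrics(tbl, "g1", horizon = 8)
  overall_c <- harrells_c(tbl$time, tbl$cause == 1, tbl$.risk, 8)
  expect_equal(one$value[one$metric == "harrell_c"], overall_c$value)
  # identical data in two groups -> identical metrics
  dup <- dplyr::bind_rows(dplyr::mutate(tbl, g = "x"),
                          dplyr::mutate(tbl, g = "y"))
  two <- subgroup_metrics(dup, "g", horizon = 8)
  wide <- tidyr::pivot_wider(two[c("level", "metric", "value")],
                             names_from = "level", values_from = "value")
  expect_equal(wide$x, wide$y)
  # sparse group flagged not estimable
  tbl$g3 <- c("tiny", rep("rest", 399))
  sparse <- subgroup_metrics(tbl, "g3", horizon = 8)
  expect_false(any(sparse$estimable[sparse$level == "tiny"]))
})

test_that("discrimination weakens across strata when the signal fades", {
  mono <- 0
  for (r in 1:25) {
    set.seed(300 + r)
    n <- 1200
    stage <- sample(1:3, n, TRUE)
    x <- rnorm(n)
    beta <- c(1.4, 0.7, 0.1)[stage]      # effect fades with stage
    cfg <- sim_config(n_subjects = n, censor_rate = 0.02, p_base = 0.3,
                      seed = r, beta_sub = c(x = 1), beta_competing = c(x = 0))
    ev <- simulate_event_times(cbind(x = x * beta), cfg)
    cs <- vapply(1:3, function(s) {
      idx <- stage == s
      harrells_c(ev$time[idx], ev$cause[idx] == 1, x[idx], 10)$value
    }, 0)
    mono <- mono + (cs[1] > cs[2] && cs[2] > cs[3])
  }
  expect_gte(mono / 25, 0.8)
})
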