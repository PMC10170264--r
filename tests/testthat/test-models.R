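test_that("fractional polynomial bases follow the repeated-power convention", {
  x <- seq(1, 10, length.out = 50)
  b <- fp_basis(x, c(2, 2), shift = 0, scale = 1)
  expect_equal(b[, 1], x^2, ignore_attr = TRUE)
  expect_equal(b[, 2], x^2 * log(x), ignore_attr = TRUE)
  b0 <- fp_basis(x, 0, shift = 0, scale = 1)
  expect_equal(b0[, 1], log(x), ignore_attr = TRUE)
  expect_error(fp_basis(x, c(1, 2, 3)), "1:2|powers")
  expect_error(select_fp(rep(1, 100), function(b) 0), "distinct")
})

test_that("FP selection recovers linear and quadratic shapes in most replicates", {
  hits_lin <- hits_quad <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 400
    x <- runif(n, 1, 10)
    # cloglog-linear outcome in x -> linear spec should survive the closed test
    eta_lin <- -2 + 0.25 * x
    y_lin <- rbinom(n, 1, 1 - exp(-exp(eta_lin))) + rnorm(n, 0, 0.05)
    sp_lin <- select_fp(x, fp_fitter_pseudo(y_lin))
    hits_lin <- hits_lin + (sp_lin$selected == "linear")
    # U-shaped outcome (a parabola in x cannot be captured by any
    # monotone degree-1 transform) -> a second-degree spec should win
    eta_quad <- -2.5 + 0.15 * (x - 5.5)^2
    y_quad <- rbinom(n, 1, 1 - exp(-exp(eta_quad))) + rnorm(n, 0, 0.05)
    sp_quad <- select_fp(x, fp_fitter_pseudo(y_quad))
    hits_quad <- hits_quad + (sp_quad$selected == "fp2")
  }
  expect_gt(hits_lin, reps / 2)
  expect_gt(hits_quad, reps / 2)
})

test_that("the predictor-selection rule is exact and permutation invariant", {
  tbl <- tibble::tibble(
    term = c("a", "b", "c_fp1", "d", "e"),
    variable = c("a", "b", "c", "d", "e"),
    type = c("binary", "binary", "continuous", "binary", "categorical"),
    estimate = log(c(1.05, 1.25, 1.5, 0.85, 1.2)),
    se = 1, df = Inf,
    p = c(0.001, 0.004, 0.02, 0.5, 0.002))
  tbl$hr <- exp(tbl$estimate)
  sel <- select_predictors(tbl)
  expect_false("a" %in% sel)   # HR 1.05 at P 0.001: magnitude fails
  expect_true("b" %in% sel)    # HR 1.25 at P 0.004: both pass
  expect_false("c" %in% sel)   # continuous at P 0.02: significance fails
  expect_false("d" %in% sel)   # magnitude passes, P fails
  expect_true("e" %in% sel)
  perm <- tbl[sample(nrow(tbl)), ]
  expect_setequal(select_predictors(perm), sel)
  # boundary behaviour is strict
  tb <- tibble::tibble(term = "z", variable = "z", type = "binary",
                       estimate = log(1.1), se = 1, df = Inf, p = 0.005,
                       hr = 1.1)
  expect_length(select_predictors(tb), 0)
})

test_that("Cox risk transform follows 1 - S0^exp(lp)", {
  mod <- structure(list(
    coefficients = tibble::tibble(term = "x", estimate = log(2)),
    predictors = "x", fp_specs = list(), horizon = 10,
    centers = c(x = 0), s0 = 0.9), class = "crp_cox")
  nd <- tibble::tibble(x = c(0, 1))
  r <- predict(mod, nd)
  expect_equal(r[1], 1 - 0.9)          # lp = 0 -> 1 - S0
  expect_equal(r[2], 1 - 0.9^2)        # lp = log 2 -> 1 - 0.9^2 = 0.19
  mod$s0 <- 1
  expect_equal(predict(mod, nd), c(0, 0))  # S0 = 1 -> risk 0 regardless
})

test_that("Cox fitting recovers simulated log hazard ratios and flags bad input", {
  set.seed(81)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  lp <- 0.9 * x
  t_event <- rexp(n, 0.1 * exp(lp)); cens <- rexp(n, 0.05)
  d <- tibble::tibble(id = 1:n, x = x,
                      time = pmin(t_event, cens, 10),
                      cause = as.integer(t_event <= pmin(cens, 10)),
                      region = sample(1:4, n, TRUE))
  pooled <- suppressWarnings(fit_cox_full(d, predictors = "x"))
  expect_gt(pooled$estimate[pooled$term == "x"], 0)
  expect_lt(abs(pooled$estimate[pooled$term == "x"] - 0.9), 0.25)
  d0 <- dplyr::mutate(d, cause = 0L)
  expect_error(fit_cox_full(d0, predictors = "x"), "no events")
})

test_that("final Cox fit is a deterministic function of the stack", {
  ch <- small_cohort(1500, seed = 83)
  st <- impute_chained(ch, m = 2, n_cycles = 2, seed = 3)
  m1 <- fit_cox(st, c("age", "stage"), horizon = 10)
  m2 <- fit_cox(st, c("age", "stage"), horizon = 10)
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate)
  expect_equal(m1$s0, m2$s0)
  risks <- predict(m1, st$imputations[[1]])
  expect_true(all(risks >= 0 & risks <= 1))
})

test_that("cloglog risk transform is the inverse link and is monotone", {
  mod <- structure(list(
    coefficients = tibble::tibble(term = c("(Intercept)", "x"),
                                  estimate = c(0, 1)),
    predictors = "x", fp_specs = list(), horizon = 10),
    class = "crp_cloglog")
  r0 <- predict(mod, tibble::tibble(x = 0))
  expect_equal(r0, 1 - exp(-1))                     # lp = 0 -> 0.6321
  expect_equal(predict(mod, tibble::tibble(x = -30)), 0, tolerance = 1e-10)
  xs <- tibble::tibble(x = seq(-3, 3, 0.5))
  expect_true(all(diff(predict(mod, xs)) > 0))
  # round trip through the link
  lp <- seq(-4, 2, 0.5)
  p <- 1 - exp(-exp(lp))
  expect_equal(log(-log(1 - p)), lp, tolerance = 1e-12)
})

test_that("an intercept-only pseudovalue model reproduces the AJ estimate", {
  d <- make_cr_data(400, seed = 85)
  pv <- pseudo_values(d$time, d$cause, 6)
  fit <- suppressWarnings(stats::glm(
    y ~ 1, data = data.frame(y = pv$values),
    family = stats::quasi(link = "cloglog", variance = "constant"),
    mustart = pmin(pmax(pv$values, 0.01), 0.99)))
  implied <- 1 - exp(-exp(coef(fit)[[1]]))
  expect_equal(implied, pv$full_sample_estimate, tolerance = 1e-6)
})

test_that("pseudovalue cloglog fitting validates its inputs", {
  ch <- small_cohort(400, seed = 87)
  pv <- pseudo_values(ch$time, ch$cause, 10)$values
  expect_error(fit_pseudo_cloglog(ch, pv, character(0)), "empty")
  expect_error(fit_pseudo_cloglog(ch, rep(0.3, nrow(ch)), "age"), "degenerate")
})

test_that("events per parameter is plain division with guarded input", {
  expect_equal(events_per_parameter(100, 100), 1)
  expect_equal(events_per_parameter(0, 10), 0)
  expect_error(events_per_parameter(10, 0), "> 0")
})
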