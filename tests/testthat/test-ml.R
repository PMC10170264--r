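test_that("constant pseudovalue targets give constant predictions", {
  set.seed(90)
  X <- matrix(runif(1000), 500, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0.3, 500)
  sp <- ml_spec("gbt")
  sp$tuned <- ml_default_config(sp)
  sp$tuned[c("max_depth", "eta", "nrounds", "subsample")] <-
    list(1, 0.1, 200, 0.5)
  sp <- fit_pseudo_ml(sp, X, y, seed = 1)
  expect_equal(max(abs(predict(sp, X, type = "raw") - 0.3)), 0,
               tolerance = 1e-6)
  nn <- mlp_fit(X, y, hidden = 30, lr = 0.05, epochs = 50, batch = 64,
                seed = 1)
  expect_lt(max(abs(mlp_forward(nn, X) - 0.3)), 0.05)
})

test_that("predictions are clipped to probabilities", {
  sp <- ml_spec("gbt")
  set.seed(91)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(-0.4, 150), rep(1.6, 150))   # forces raw values outside [0, 1]
  sp$tuned <- ml_default_config(sp)
  sp$tuned[c("eta", "nrounds", "alpha", "gamma", "lambda")] <-
    list(0.1, 150, 0, 0, 0)
  sp <- fit_pseudo_ml(sp, X, y, seed = 2)
  raw <- predict(sp, X, type = "raw")
  risk <- predict(sp, X)
  expect_true(any(raw < 0) && any(raw > 1))
  expect_equal(risk, pmin(pmax(raw, 0), 1))
  expect_true(all(risk >= 0 & risk <= 1))
})

test_that("gbt fits are reproducible under a fixed seed", {
  set.seed(92)
  X <- matrix(rnorm(800), 400, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] * 0.3 + rnorm(400, 0, 0.1)
  sp <- ml_spec("gbt")
  p1 <- predict(fit_pseudo_ml(sp, X, y, seed = 7), X, type = "raw")
  p2 <- predict(fit_pseudo_ml(sp, X, y, seed = 7), X, type = "raw")
  expect_identical(p1, p2)
})

test_that("both learners recover a strong single-covariate signal", {
  set.seed(93)
  n <- 5000
  x <- rnorm(n)
  cfg <- sim_config(n_subjects = n, censor_rate = 0, p_base = 0.25, seed = 5,
                    beta_sub = c(x = 1.2), beta_competing = c(x = 0.1))
  ev <- simulate_event_times(cbind(x = x), cfg)
  ps <- pseudo_values(ev$time, ev$cause, 10)$values
  for (ln in c("gbt", "ffnn")) {
    X <- cbind(x = if (ln == "ffnn") (x - min(x)) / diff(range(x)) else x)
    sp <- fit_pseudo_ml(ml_spec(ln), X, ps, seed = 5)
    expect_gt(cor(predict(sp, X), ev$truth, method = "spearman"), 0.8)
  }
})

test_that("tuning honours its contract", {
  set.seed(94)
  X <- matrix(rnorm(1200), 600, 2, dimnames = list(NULL, c("a", "b")))
  y <- 0.4 * X[, 1] + rnorm(600, 0, 0.2)
  sp <- ml_spec("gbt", ranges = list(nrounds = c(1, 60)))
  expect_error(tune_hyperparameters(sp, X, y, k_folds = 1), "k_folds")
  expect_error(tune_hyperparameters(sp, X, y, budget = 0), "budget")

  t1 <- tune_hyperparameters(sp, X, y, budget = 1, seed = 3)
  expect_true(all(names(t1$tuned) %in% names(sp$ranges)))
  # tuned CV-RMSE never exceeds the default configuration's
  expect_lte(attr(t1, "cv_rmse"), attr(t1, "cv_default_rmse"))
  # larger budget with the same seed stream never does worse
  t4 <- tune_hyperparameters(sp, X, y, budget = 4, seed = 3)
  t8 <- tune_hyperparameters(sp, X, y, budget = 8, seed = 3)
  expect_lte(attr(t4, "cv_rmse"), attr(t1, "cv_rmse"))
  expect_lte(attr(t8, "cv_rmse"), attr(t4, "cv_rmse"))
  # candidate streams are prefix stable
  expect_equal(attr(t8, "cv_table")[seq_along(attr(t4, "cv_table"))],
               attr(t4, "cv_table"))
})

test_that("tuned configurations outside the declared space are rejected", {
  sp <- ml_spec("gbt")
  sp$tuned <- ml_default_config(sp)
  sp$tuned$eta <- 5
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_pseudo_ml(sp, X, rnorm(50)), "outside")
})

test_that("ffnn preprocessing scales to [0, 1] and reuses training constants", {
  ch <- small_cohort(400, seed = 95)
  st <- impute_chained(ch, m = 2, n_cycles = 1, seed = 1)
  d <- st$imputations[[1]]
  pp <- ml_preprocess(d, c("age", "stage", "er"), scale = TRUE)
  expect_true(all(pp$X >= 0 & pp$X <= 1))
  # new data transformed with training constants, clipped into range
  d2 <- d; d2$age <- d2$age + 50
  X2 <- ml_preprocess(d2, c("age", "stage", "er"), pp$preproc)$X
  expect_true(all(X2 <= 1))
  expect_error(ml_preprocess(d[c("age", "er", "time", "cause")],
                             c("age", "er", "stage"), pp$preproc),
               "stage")
})
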