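test_that("cohorts are reproducible under a fixed seed and differ across seeds", {
  cfg <- sim_config(n_subjects = 500, seed = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c <- simulate_cohort(sim_config(n_subjects = 500, seed = 5))
  expect_false(isTRUE(all.equal(a$time, c$time)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_subjects = 0), "positive")
  expect_error(sim_config(p_base = 1.2), "0, 1")
  expect_error(sim_config(n_regions = 1), ">= 2")
  expect_error(sim_config(period2_rate_multiplier = 0), "> 0")
  expect_error(sim_config(beta_sub = numeric(0)), "non-empty")
})

test_that("null covariate effects recover the baseline mixture probability", {
  cfg <- sim_config(n_subjects = 20000, censor_rate = 0, horizon = 1e6,
                    p_base = 0.2, seed = 7)
  X <- matrix(0, 20000, 2, dimnames = list(NULL, c("z_age", "z_age2")))
  set.seed(7)
  ev <- simulate_event_times(X, cfg)
  se <- sqrt(0.2 * 0.8 / 20000)
  expect_lt(abs(mean(ev$cause == 1) - 0.2), 3 * se)
})

test_that("no censoring before the horizon when the censoring rate is zero", {
  cfg <- sim_config(n_subjects = 2000, censor_rate = 0, seed = 3)
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$cause != 0 | ch$time == cfg$horizon))
})

test_that("the empirical Aalen-Johansen CIF matches the analytic truth", {
  n <- 50000
  cfg <- sim_config(n_subjects = n, censor_rate = 0, seed = 11)
  set.seed(11)
  cov <- draw_covariates(n, cfg)
  ev <- simulate_event_times(cohort_design(cov), cfg)
  cif <- aj_cif_at(ev$time, ev$cause, cfg$horizon)
  mc_se <- sqrt(cif * (1 - cif) / n)
  expect_lt(abs(cif - mean(ev$truth)), 3 * mc_se)
})

test_that("missingness follows the configured logistic model", {
  n <- 20000
  cfg <- sim_config(n_subjects = n, seed = 13,
                    mar_config = list(bmi = c(0, 0, 0)))
  ch <- simulate_cohort(cfg)
  # intercept-only logit 0 -> 50% masked
  expect_lt(abs(mean(is.na(ch$bmi)) - 0.5), 3 * sqrt(0.25 / n))

  cfg2 <- sim_config(n_subjects = n, seed = 13,
                     mar_config = list(bmi = c(-1, 0, 1.5)))
  ch2 <- simulate_cohort(cfg2)
  for (p in 1:2) {
    sel <- ch2$period == p
    expected <- plogis(-1 + 1.5 * (p == 1))
    expect_lt(abs(mean(is.na(ch2$bmi[sel])) - expected),
              3 * sqrt(expected * (1 - expected) / sum(sel)))
  }
  # impossible missingness under -Inf intercepts
  cfg3 <- sim_config(n_subjects = 1000, seed = 13,
                     mar_config = list(bmi = c(-Inf, 0, 0)))
  expect_false(anyNA(simulate_cohort(cfg3)$bmi))
  # conditioning on a maskable variable is rejected
  expect_error(inject_missingness(ch, list(age = c(0, 0, 0))), "maskable")
})

test_that("period truncation censors follow-up at the boundary", {
  ch <- tibble::tibble(id = 1:3, entry = c(4, 9.5, 12), period = c(1L, 1L, 2L),
                       time = c(8, 0.2, 5), cause = c(1L, 1L, 1L))
  tr <- truncate_followup(ch, 10)
  # event after the boundary: censored at boundary - entry
  expect_equal(tr$period1$cause[tr$period1$id == 1], 0L)
  expect_equal(tr$period1$time[tr$period1$id == 1], 6)
  # events inside period 1 and all of period 2 are untouched
  expect_equal(tr$period1$cause[tr$period1$id == 2], 1L)
  expect_identical(tr$period2, ch[3, ])
  expect_error(truncate_followup(dplyr::mutate(ch, entry = entry + 20), 10),
               "boundary")
})

test_that("truncation never increases the event count", {
  ch <- small_cohort(3000, seed = 17)
  tr <- truncate_followup(ch, 10)
  expect_lte(sum(tr$period1$cause == 1) + sum(tr$period2$cause == 1),
             sum(ch$cause == 1))
})

test_that("raising the censoring rate never adds observed events (coupled draws)", {
  counts <- vapply(c(0, 0.03, 0.1, 0.3), function(cr) {
    cfg <- sim_config(n_subjects = 4000, censor_rate = cr, seed = 19)
    sum(simulate_cohort(cfg)$cause == 1)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cohorts survive a text round trip", {
  ch <- small_cohort(300, seed = 23)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_equal(back$time, ch$time)
  expect_identical(back$stage, ch$stage)
  expect_identical(is.na(back$bmi), is.na(ch$bmi))
})
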