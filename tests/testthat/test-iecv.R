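cohort_iecv <- small_cohort(2500, seed = 131)
config_fast <- iecv_config(models = c("cox", "crr"), m = 2, n_cycles = 2,
                           seed = 131)

test_that("a single-model configuration yields exactly that model's tables", {
  res <- suppressWarnings(run_iecv(cohort_iecv,
                                   iecv_config(models = "cox", m = 2,
                                               n_cycles = 2, seed = 131)))
  expect_setequal(unique(res$meta$model), "cox")
  expect_setequal(unique(res$cluster_metrics$model), "cox")
  expect_setequal(unique(res$cluster_metrics$metric),
                  c("harrell_c", "slope", "citl"))
  expect_error(iecv_config(models = character(0)), "non-empty")
})

test_that("the IECV run is deterministic under a fixed seed", {
  r1 <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  r2 <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  expect_equal(r1$meta, r2$meta)
  expect_equal(r1$predictions, r2$predictions)
})

test_that("pooled rows delegate exactly to the meta-analysis module", {
  res <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  for (mm in c("cox", "crr")) {
    cl <- dplyr::filter(res$cluster_metrics, .data$model == mm,
                        .data$metric == "slope", is.finite(.data$value),
                        .data$se > 0)
    ref <- hksj_random_effects(cl$value, cl$se)
    got <- dplyr::filter(res$meta, .data$model == mm, .data$metric == "slope")
    expect_equal(got$estimate, ref$estimate)
    expect_equal(got$pi_low, ref$pi_low)
  }
  # every pooled row carries a CI and a PI
  expect_true(all(is.finite(res$meta$ci_low) & is.finite(res$meta$ci_high)))
  expect_true(all(is.finite(res$meta$pi_low) & is.finite(res$meta$pi_high)))
})

test_that("training and test periods never share follow-up windows", {
  res <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  expect_true(all(res$audit$overlap == 0))
  expect_equal(nrow(res$audit), length(unique(cohort_iecv$region)))
  expect_true(all(nchar(res$audit$train_hash) == 8))
})

test_that("final models serialise to text and reload bit for bit", {
  fin <- suppressWarnings(
    fit_final_models(cohort_iecv,
                     iecv_config(models = c("cox", "crr"), m = 2,
                                 n_cycles = 2, seed = 131)))
  probe <- cohort_iecv[1:20, ]
  for (v in names(default_mar_config()))
    probe[[v]] <- probe[[paste0(".orig_", v)]]
  for (nm in c("cox", "crr")) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model(fin$models[[nm]], path)
    back <- read_model(path)
    expect_identical(predict(back, probe), predict(fin$models[[nm]], probe))
  }
})

test_that("all four strategies emit probabilities on fresh subjects", {
  ch <- small_cohort(1800, seed = 133)
  fin <- suppressWarnings(
    fit_final_models(ch, iecv_config(m = 2, n_cycles = 2, tuner_budget = 1,
                                     tune_max_rows = 1200, seed = 133)))
  nd <- small_cohort(1000, seed = 134)
  for (v in names(default_mar_config()))
    nd[[v]] <- nd[[paste0(".orig_", v)]]
  for (nm in c("cox", "crr")) {
    r <- predict(fin$models[[nm]], nd)
    expect_true(all(r >= 0 & r <= 1))
  }
  for (nm in c("gbt", "ffnn")) {
    X <- ml_preprocess(nd, fin$selection$crr, fin$models[[nm]]$preproc)$X
    r <- predict(fin$models[[nm]], X)
    expect_true(all(r >= 0 & r <= 1))
  }
  # Cox and cloglog risks agree strongly when competing events are rare
  r_cox <- predict(fin$models$cox, nd)
  r_crr <- predict(fin$models$crr, nd)
  expect_gt(cor(r_cox, r_crr, method = "spearman"), 0.9)
})

test_that("reports carry the full table schema and are regenerable", {
  res <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  dir <- withr::local_tempdir()
  files <- make_report(res, dir)
  expect_true(file.exists(file.path(dir, "meta_summary.tsv")))
  meta_tbl <- utils::read.delim(file.path(dir, "meta_summary.tsv"))
  expect_true(all(c("ci_low", "ci_high", "pi_low", "pi_high") %in%
                    names(meta_tbl)))
  expect_true(all(is.finite(meta_tbl$pi_low)))
  audit_tbl <- utils::read.delim(file.path(dir, "leakage_audit.tsv"))
  expect_equal(sum(audit_tbl$overlap), 0)
  # regenerating from the same result reproduces the tables byte for byte
  dir2 <- withr::local_tempdir()
  make_report(res, dir2)
  expect_identical(readLines(file.path(dir, "meta_summary.tsv")),
                   readLines(file.path(dir2, "meta_summary.tsv")))
})

test_that("tidiers and plots expose the result surfaces", {
  res <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$leakage, 0)
  p <- plot_forest(res, "slope")
  expect_s3_class(p, "ggplot")
  dc <- decision_curve(res$predictions$time, res$predictions$cause,
                       res$predictions$risk_crr, horizon = 10,
                       thresholds = c(0.05, 0.2))
  expect_s3_class(ggplot2::autoplot(dc), "ggplot")
  cc <- smoothed_calibration_curve(res$predictions$risk_crr,
                                   res$predictions$pseudo_cif)
  expect_s3_class(ggplot2::autoplot(cc), "ggplot")
})

test_that("meta-regression over regions runs end to end", {
  res <- suppressWarnings(run_iecv(cohort_iecv, config_fast))
  rc <- region_covariates(cohort_iecv)
  mr <- iecv_meta_regression(res, rc, vars = c("age_sd", "nonwhite_pct"))
  expect_true(all(c("model", "metric", "r2") %in% names(mr)))
  ok <- mr$r2[is.finite(mr$r2)]
  expect_true(all(ok >= 0 & ok <= 100))
})
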