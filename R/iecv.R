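#' Configuration for internal-external cross validation
#'
#' @param models Subset of `c("cox", "crr", "gbt", "ffnn")`: Cox
#'   proportional hazards, pseudovalue cloglog competing-risks regression,
#'   gradient-boosted trees, feed-forward neural network.
#' @param horizon Prediction horizon in years (default 10).
#' @param period_boundary Calendar boundary between entry periods.
#' @param m Number of imputations (default 5 at desk scale).
#' @param n_cycles Chained-equation cycles (default 10).
#' @param tuner_budget Random-search candidates per ML tuning (default 15).
#' @param k_folds Cross-validation folds inside tuning (default 5).
#' @param tune_max_rows Row cap for tuning fits (default 4000; final fits
#'   use all rows).
#' @param gbt_ranges,ffnn_ranges Hyperparameter range overrides passed to
#'   [ml_spec()]; the desk-scale defaults cap boosting rounds at 150 and
#'   hidden layers at 2.
#' @param thresholds Decision-curve threshold grid.
#' @param fp_vars Continuous variables eligible for fractional-polynomial
#'   terms.
#' @param fp_alpha Closed-test level for FP selection.
#' @param train_mode `"geographic_temporal"` (held-out region excluded from
#'   training entirely, the default) or `"temporal_only"` (train on all
#'   regions' period-1 data).
#' @param cluster Clustering column for robust Cox errors.
#' @param seed Master seed; per-stage seeds are derived from it and logged.
#' @return List of class `crp_iecv_config`.
#' @export
iecv_config <- function(models = c("cox", "crr", "gbt", "ffnn"),
                        horizon = 10, period_boundary = 10,
                        m = 5, n_cycles = 10,
                        tuner_budget = 15, k_folds = 5, tune_max_rows = 4000,
                        gbt_ranges = list(nrounds = c(1, 150)),
                        ffnn_ranges = list(n_layers = c(1, 2)),
                        thresholds = seq(0.01, 0.5, by = 0.01),
                        fp_vars = c("age", "bmi", "deprivation"),
                        fp_alpha = 0.05,
                        train_mode = c("geographic_temporal", "temporal_only"),
                        cluster = "region", seed = 1L) {
  if (length(models) == 0) stop("`models` must be non-empty", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  structure(list(models = models, horizon = horizon,
                 period_boundary = period_boundary, m = m,
                 n_cycles = n_cycles, tuner_budget = tuner_budget,
                 k_folds = k_folds, tune_max_rows = tune_max_rows,
                 gbt_ranges = gbt_ranges, ffnn_ranges = ffnn_ranges,
                 thresholds = thresholds, fp_vars = fp_vars,
                 fp_alpha = fp_alpha,
                 train_mode = match.arg(train_mode),
                 cluster = cluster, seed = as.integer(seed)),
            class = "crp_iecv_config")
}

# Polynomial rolling hash (mod 2^31 - 1) of a sorted id vector, for the
# leakage audit trail.
hash_ids <- function(ids) {
  bytes <- as.integer(charToRaw(paste(sort(ids), collapse = ",")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Shared preparation: imputation, FP selection, full-model predictor
# selection. Used by both run_iecv() and fit_final_models().
prepare_cohort_models <- function(cohort, config) {
  stack <- impute_chained(cohort, m = config$m, n_cycles = config$n_cycles,
                          seed = config$seed + 101L)

  cc <- stats::complete.cases(cohort[candidate_predictors()])
  comp <- cohort[cc, ]
  pseudo_full <- pseudo_values(cohort$time, cohort$cause, config$horizon,
                               "cif_cause1")$values

  fp_cox <- fp_cloglog <- list()
  for (v in config$fp_vars) {
    fit_cox_ctx <- fp_fitter_cox(comp$time, comp$cause)
    fp_cox[[v]] <- select_fp(comp[[v]], fit_cox_ctx, alpha = config$fp_alpha)
    fit_ps_ctx <- fp_fitter_pseudo(pseudo_full[cc])
    fp_cloglog[[v]] <- select_fp(comp[[v]], fit_ps_ctx, alpha = config$fp_alpha)
  }

  sel_cox <- sel_crr <- candidate_predictors()
  if ("cox" %in% config$models) {
    full_cox <- suppressWarnings(
      fit_cox_full(stack, candidate_predictors(), fp_cox, config$cluster))
    sel_cox <- select_predictors(full_cox)
    if (length(sel_cox) == 0) sel_cox <- candidate_predictors()
  }
  if (any(c("crr", "gbt", "ffnn") %in% config$models)) {
    full_crr <- fit_pseudo_cloglog_full(stack, pseudo_full,
                                        candidate_predictors(), fp_cloglog)
    sel_crr <- select_predictors(full_crr)
    if (length(sel_crr) == 0) sel_crr <- candidate_predictors()
  }
  list(stack = stack, fp_cox = fp_cox, fp_cloglog = fp_cloglog,
       sel_cox = sel_cox, sel_crr = sel_crr, pseudo_full = pseudo_full)
}

#' Run internal-external cross validation
#'
#' Orchestrates the full comparative evaluation: multiple imputation on the
#' whole cohort, fractional-polynomial and predictor selection from full
#' data, then one cycle per region in which models are fitted to period-1
#' data from the other regions (follow-up truncated at the period
#' boundary), machine-learning hyperparameters are tuned inside the
#' training set by k-fold cross validation (nested), pseudovalues are
#' computed separately in the training and test strata, predictions are
#' made on the held-out region's period-2 data, and region-level metrics
#' (per imputation, Rubin-pooled) are meta-analysed with the HKSJ method.
#'
#' @param cohort Cohort tibble from [simulate_cohort()] or [read_cohort()].
#' @param config An [iecv_config()].
#' @return Object of class `crp_iecv`: `cluster_metrics` (per model x
#'   region x metric, pooled over imputations), `per_imputation` metrics,
#'   `meta` (HKSJ pooled rows with CI and PI), `predictions` (pooled
#'   individual-level predictions with stratum pseudovalues), `audit`
#'   (train/test id hashes and overlap counts per cycle), `selection`,
#'   `config`, `seeds`.
#' @export
run_iecv <- function(cohort, config = iecv_config()) {
  stopifnot(inherits(config, "crp_iecv_config"))
  regions <- sort(unique(cohort$region))
  if (length(regions) < 3)
    stop("need >= 3 regions with events in both periods", call. = FALSE)

  prep <- prepare_cohort_models(cohort, config)
  split <- truncate_followup(cohort, config$period_boundary)
  p1_ids <- split$period1$id
  p2_ids <- split$period2$id

  per_imp <- list(); audits <- list(); preds_out <- list()
  for (r in regions) {
    test <- dplyr::filter(split$period2, .data$region == r)
    if (sum(test$cause == 1) == 0) {
      warning("region ", r, " has no test-period events; excluded", call. = FALSE)
      next
    }
    train <- if (config$train_mode == "geographic_temporal")
      dplyr::filter(split$period1, .data$region != r) else split$period1

    audits[[as.character(r)]] <- tibble::tibble(
      region = r, n_train = nrow(train), n_test = nrow(test),
      train_hash = hash_ids(train$id), test_hash = hash_ids(test$id),
      overlap = length(intersect(train$id, test$id)))

    res <- iecv_cycle(train, test, prep, config, r)
    per_imp[[as.character(r)]] <- res$metrics
    preds_out[[as.character(r)]] <- res$predictions
  }
  per_imp <- dplyr::bind_rows(per_imp)
  audit <- dplyr::bind_rows(audits)

  cluster_metrics <- per_imp |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(~ pool_metric_over_imputations(.x)) |>
    dplyr::ungroup()

  meta <- cluster_metrics |>
    dplyr::filter(is.finite(.data$value), is.finite(.data$se), .data$se > 0) |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::group_modify(~ hksj_random_effects(.x$value, .x$se)) |>
    dplyr::ungroup()

  out <- list(cluster_metrics = cluster_metrics, per_imputation = per_imp,
              meta = meta, predictions = dplyr::bind_rows(preds_out),
              audit = audit,
              selection = list(cox = prep$sel_cox, crr = prep$sel_crr,
                               fp_cox = prep$fp_cox,
                               fp_cloglog = prep$fp_cloglog),
              config = config,
              seeds = c(master = config$seed, impute = config$seed + 101L))
  class(out) <- "crp_iecv"
  out
}

# One IECV cycle: fit the requested models on the training stratum and
# evaluate per imputation on the held-out test stratum.
iecv_cycle <- function(train, test, prep, config, r) {
  m <- config$m
  tr_idx <- match(train$id, prep$stack$imputations[[1]]$id)
  te_idx <- match(test$id, prep$stack$imputations[[1]]$id)
  # imputed covariates with the truncated follow-up of this cycle
  imp_train <- lapply(prep$stack$imputations, function(d) {
    d <- d[tr_idx, ]; d$time <- train$time; d$cause <- train$cause; d
  })
  imp_test <- lapply(prep$stack$imputations, function(d) {
    d <- d[te_idx, ]; d$time <- test$time; d$cause <- test$cause; d
  })
  tr_stack <- structure(list(imputations = imp_train, m = m,
                             vars = prep$stack$vars, seed = prep$stack$seed),
                        class = "crp_imputation_stack")

  ps_tr_cif <- pseudo_values(train$time, train$cause, config$horizon,
                             "cif_cause1")$values
  ps_te_cif <- pseudo_values(test$time, test$cause, config$horizon,
                             "cif_cause1")$values
  ps_te_km <- pseudo_values(test$time, test$cause, config$horizon,
                            "km_failure")$values

  risks <- list()
  if ("cox" %in% config$models) {
    mod <- fit_cox(tr_stack, prep$sel_cox, prep$fp_cox, config$cluster,
                   config$horizon)
    risks$cox <- vapply(imp_test, function(d) predict(mod, d),
                        numeric(nrow(test)))
  }
  if ("crr" %in% config$models) {
    mod <- fit_pseudo_cloglog(tr_stack, ps_tr_cif, prep$sel_crr,
                              prep$fp_cloglog, config$horizon)
    risks$crr <- vapply(imp_test, function(d) predict(mod, d),
                        numeric(nrow(test)))
  }
  for (learner in intersect(c("gbt", "ffnn"), config$models)) {
    spec <- ml_spec(if (learner == "gbt") "gbt" else "ffnn",
                    ranges = if (learner == "gbt") config$gbt_ranges
                             else config$ffnn_ranges)
    pp <- ml_preprocess(imp_train[[1]], prep$sel_crr,
                        scale = learner == "ffnn")
    Xtr <- do.call(rbind, lapply(imp_train, function(d)
      ml_preprocess(d, prep$sel_crr, pp$preproc)$X))
    ytr <- rep(ps_tr_cif, m)
    seed_r <- config$seed + 1000L * match(learner, c("gbt", "ffnn")) + r
    spec <- tune_hyperparameters(spec, Xtr, ytr, k_folds = config$k_folds,
                                 budget = config$tuner_budget, seed = seed_r,
                                 max_rows = config$tune_max_rows)
    spec <- fit_pseudo_ml(spec, Xtr, ytr, seed = seed_r)
    risks[[learner]] <- vapply(imp_test, function(d)
      predict(spec, ml_preprocess(d, prep$sel_crr, pp$preproc)$X),
      numeric(nrow(test)))
  }

  metrics <- purrr::imap_dfr(risks, function(rk, model) {
    purrr::map_dfr(seq_len(m), function(i) {
      ri <- rk[, i]
      disc <- if (model == "cox")
        harrells_c(test$time, test$cause == 1, ri, config$horizon)
      else ipcw_c_index(test$time, test$cause, ri, config$horizon)
      ps <- if (model == "cox") ps_te_km else ps_te_cif
      cal <- tryCatch(calibration_slope_citl(ps, ri), error = function(e)
        tibble::tibble(metric = c("slope", "citl"), value = NA_real_,
                       se = NA_real_))
      dplyr::bind_rows(disc, cal) |>
        dplyr::mutate(model = model, region = r, .imp = i)
    })
  })

  pred_tbl <- test["id"]
  pred_tbl$region <- r
  pred_tbl$time <- test$time; pred_tbl$cause <- test$cause
  for (nm in c("age", "stage", "ethnicity", "bmi", "deprivation"))
    if (nm %in% names(test)) pred_tbl[[nm]] <- test[[nm]]
  pred_tbl$pseudo_km <- ps_te_km
  pred_tbl$pseudo_cif <- ps_te_cif
  for (model in names(risks)) pred_tbl[[paste0("risk_", model)]] <-
    rowMeans(risks[[model]])
  list(metrics = metrics, predictions = pred_tbl)
}

#' @export
print.crp_iecv <- function(x, ...) {
  cat("<crp_iecv>", length(unique(x$audit$region)), "cycles;",
      paste(x$config$models, collapse = "/"), "\n")
  print(x$meta)
  invisible(x)
}

#' Fit the four final models on the whole cohort
#'
#' Full-cohort counterparts of the IECV training fits: imputation, FP and
#' predictor selection, Cox and pseudovalue cloglog fits, and tuned ML fits
#' on the stacked imputations, with pseudovalues computed on the overall
#' cohort.
#'
#' @inheritParams run_iecv
#' @return Object of class `crp_final_models`: `models` (named list),
#'   `selection`, `config`.
#' @export
fit_final_models <- function(cohort, config = iecv_config()) {
  prep <- prepare_cohort_models(cohort, config)
  models <- list()
  if ("cox" %in% config$models)
    models$cox <- fit_cox(prep$stack, prep$sel_cox, prep$fp_cox,
                          config$cluster, config$horizon)
  if ("crr" %in% config$models)
    models$crr <- fit_pseudo_cloglog(prep$stack, prep$pseudo_full,
                                     prep$sel_crr, prep$fp_cloglog,
                                     config$horizon)
  for (learner in intersect(c("gbt", "ffnn"), config$models)) {
    spec <- ml_spec(if (learner == "gbt") "gbt" else "ffnn",
                    ranges = if (learner == "gbt") config$gbt_ranges
                             else config$ffnn_ranges)
    pp <- ml_preprocess(prep$stack$imputations[[1]], prep$sel_crr,
                        scale = learner == "ffnn")
    Xtr <- do.call(rbind, lapply(prep$stack$imputations, function(d)
      ml_preprocess(d, prep$sel_crr, pp$preproc)$X))
    ytr <- rep(prep$pseudo_full, config$m)
    seed_l <- config$seed + 5000L + match(learner, c("gbt", "ffnn"))
    spec <- tune_hyperparameters(spec, Xtr, ytr, k_folds = config$k_folds,
                                 budget = config$tuner_budget, seed = seed_l,
                                 max_rows = config$tune_max_rows)
    spec <- fit_pseudo_ml(spec, Xtr, ytr, seed = seed_l)
    spec$preproc <- pp$preproc
    models[[learner]] <- spec
  }
  structure(list(models = models,
                 selection = list(cox = prep$sel_cox, crr = prep$sel_crr,
                                  fp_cox = prep$fp_cox,
                                  fp_cloglog = prep$fp_cloglog),
                 config = config),
            class = "crp_final_models")
}

#' Region-level covariate summaries for meta-regression
#'
#' Cluster covariates estimated from period-2 data: within-region SD of
#' age and BMI, mean deprivation score, and percentage belonging to the
#' non-majority ethnicity analogue.
#'
#' @param cohort Cohort tibble.
#' @param period_boundary Calendar boundary defining period 2.
#' @return Tibble with one row per region.
#' @export
region_covariates <- function(cohort, period_boundary = 10) {
  p2 <- dplyr::filter(cohort, .data$period == 2L)
  p2 |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      age_sd = stats::sd(.data$age),
      bmi_sd = stats::sd(.data$bmi, na.rm = TRUE),
      deprivation_mean = mean(.data$deprivation, na.rm = TRUE),
      nonwhite_pct = if ("ethnicity" %in% names(p2))
        100 * mean(.data$ethnicity != "white", na.rm = TRUE) else NA_real_,
      .groups = "drop")
}

#' Heterogeneity meta-regression of IECV cluster metrics
#'
#' For each model and metric, regresses the region-level estimates on
#' region covariates and reports residual I^2 and R^2.
#'
#' @param result A `crp_iecv` object.
#' @param covariates Region covariate tibble from [region_covariates()]
#'   (must include a `region` column).
#' @param vars Covariate columns to use (default all besides `region`).
#' @return Tibble: `model`, `metric`, `r2`, `i2_residual`, `tau2`,
#'   `tau2_null`.
#' @export
iecv_meta_regression <- function(result, covariates, vars = NULL) {
  stopifnot(inherits(result, "crp_iecv"))
  if (is.null(vars)) vars <- setdiff(names(covariates), "region")
  vars <- vars[vapply(covariates[vars], function(x) all(is.finite(x)), TRUE)]
  result$cluster_metrics |>
    dplyr::filter(is.finite(.data$value), .data$se > 0) |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      cv <- covariates[match(d$region, covariates$region), vars, drop = FALSE]
      mr <- tryCatch(meta_regression(d$value, d$se, cv),
                     error = function(e) NULL)
      if (is.null(mr))
        return(tibble::tibble(r2 = NA_real_, i2_residual = NA_real_,
                              tau2 = NA_real_, tau2_null = NA_real_))
      tibble::tibble(r2 = mr$r2, i2_residual = mr$i2_residual,
                     tau2 = mr$tau2, tau2_null = mr$tau2_null)
    }) |>
    dplyr::ungroup()
}
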