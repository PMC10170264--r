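#' Fit the full Cox model across imputations
#'
#' Fits a Cox proportional hazards model with all candidate predictors in
#' each completed dataset (competing deaths censored, Efron ties, robust
#' standard errors clustered on `cluster`), and pools coefficients and
#' standard errors with Rubin's rules. The pooled coefficient table is the
#' basis for the magnitude-plus-significance predictor selection rule.
#'
#' @param stack A `crp_imputation_stack` (or a plain cohort tibble, treated
#'   as a single complete dataset of m = 1; pooling then degenerates).
#' @param predictors Character vector of candidate predictors.
#' @param fp_specs Named list of `crp_fp_spec` for continuous predictors.
#' @param cluster Column name used for clustered standard errors
#'   (default `"region"`).
#' @return A `crp_pooled_coefs` tibble: one row per design term with
#'   `variable`, `type`, pooled `estimate`, `se`, `df`, `p` and `hr`.
#' @export
fit_cox_full <- function(stack, predictors = candidate_predictors(),
                         fp_specs = list(), cluster = "region") {
  datasets <- imputation_list(stack)
  fits <- lapply(datasets, function(d) {
    X <- build_design(d, predictors, fp_specs)
    n_events <- sum(d$cause == 1)
    if (n_events == 0) stop("no events of interest in the data", call. = FALSE)
    if (n_events < 10 * ncol(X))
      warning("fewer than 10 events per parameter (", n_events, " events, ",
              ncol(X), " parameters)", call. = FALSE)
    fit <- survival::coxph(survival::Surv(d$time, d$cause == 1) ~ X,
                           cluster = d[[cluster]], ties = "efron")
    list(coef = stats::setNames(stats::coef(fit), colnames(X)),
         var = stats::setNames(diag(fit$var), colnames(X)),
         X = X)
  })
  pool_coef_table(fits, intercept = FALSE)
}

imputation_list <- function(stack) {
  if (inherits(stack, "crp_imputation_stack")) stack$imputations else list(stack)
}

# Rubin-pool per-imputation coefficient fits into a tidy table.
pool_coef_table <- function(fits, intercept = FALSE) {
  est <- do.call(rbind, lapply(fits, `[[`, "coef"))
  var <- do.call(rbind, lapply(fits, `[[`, "var"))
  pooled <- if (nrow(est) >= 2) rubin_pool(est, var) else
    tibble::tibble(term = colnames(est), estimate = drop(est),
                   within = drop(var), between = 0, total = drop(var),
                   se = sqrt(drop(var)), df = Inf)
  vm <- attr(fits[[1]]$X, "var_map"); tm <- attr(fits[[1]]$X, "type_map")
  pooled$variable <- if (intercept)
    c("(Intercept)", unname(vm))[match(pooled$term, c("(Intercept)", names(vm)))]
    else unname(vm[pooled$term])
  pooled$type <- if (intercept)
    c("intercept", unname(tm))[match(pooled$term, c("(Intercept)", names(tm)))]
    else unname(tm[pooled$term])
  pooled$p <- 2 * stats::pt(abs(pooled$estimate / pooled$se),
                            df = pooled$df, lower.tail = FALSE)
  pooled$hr <- exp(pooled$estimate)
  class(pooled) <- c("crp_pooled_coefs", class(pooled))
  pooled
}

#' Magnitude-plus-significance predictor selection
#'
#' Deterministic rule applied to a pooled full-model coefficient table:
#' binary or multilevel categorical predictors are retained when any of
#' their terms has an exponentiated coefficient > `hr_high` or < `hr_low`
#' at P < `p_cat`; continuous (fractional-polynomial) terms and
#' interactions are retained at P < `p_cont`. A multilevel categorical
#' enters whole if at least one level qualifies (levels cannot enter
#' alone).
#'
#' @param pooled A `crp_pooled_coefs` table from [fit_cox_full()] or
#'   [fit_pseudo_cloglog_full()].
#' @param hr_low,hr_high Magnitude thresholds on the exponentiated
#'   coefficient (defaults 0.9 and 1.1).
#' @param p_cat,p_cont Significance thresholds (defaults 0.01).
#' @return Character vector of selected variables (order of appearance).
#' @export
select_predictors <- function(pooled, hr_low = 0.9, hr_high = 1.1,
                              p_cat = 0.01, p_cont = 0.01) {
  tbl <- pooled[pooled$type != "intercept", ]
  qualifies <- ifelse(
    tbl$type %in% c("binary", "categorical"),
    (tbl$hr > hr_high | tbl$hr < hr_low) & tbl$p < p_cat,
    tbl$p < p_cont)
  unique(tbl$variable[qualifies])
}

#' Fit the final Cox model and its baseline survival
#'
#' Refits the Cox model on the selected predictors in each completed
#' dataset, Rubin-pools coefficients, and computes the baseline survival at
#' the horizon with continuous predictors centred at their mean and
#' binary/dummy terms set to zero. Baseline survival is pooled across
#' imputations on the cumulative-hazard scale.
#'
#' @inheritParams fit_cox_full
#' @param horizon Prediction horizon in years (default 10).
#' @return A `crp_cox` model object.
#' @export
fit_cox <- function(stack, predictors, fp_specs = list(), cluster = "region",
                    horizon = 10) {
  datasets <- imputation_list(stack)
  fits <- list(); h0c <- numeric(length(datasets)); centers_acc <- NULL
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    X <- build_design(d, predictors, fp_specs)
    fit <- survival::coxph(survival::Surv(d$time, d$cause == 1) ~ X,
                           cluster = d[[cluster]], ties = "efron")
    beta <- stats::setNames(stats::coef(fit), colnames(X))
    ctr <- attr(X, "centers")
    bh <- survival::basehaz(fit, centered = FALSE)
    h0 <- c(0, bh$hazard)[findInterval(horizon, bh$time) + 1L]
    h0c[i] <- h0 * exp(sum(ctr * beta))
    fits[[i]] <- list(coef = beta, var = stats::setNames(diag(fit$var),
                                                         colnames(X)), X = X)
    centers_acc <- if (is.null(centers_acc)) ctr else centers_acc + ctr
  }
  pooled <- pool_coef_table(fits, intercept = FALSE)
  structure(list(coefficients = pooled, predictors = predictors,
                 fp_specs = fp_specs, horizon = horizon,
                 centers = centers_acc / length(datasets),
                 s0 = exp(-mean(h0c))),
            class = "crp_cox")
}

#' Predicted 10-year event probability from a Cox model
#'
#' risk = 1 - S0^exp(lp), with lp the centred linear predictor and S0 the
#' pooled baseline survival at the model horizon.
#'
#' @param object A `crp_cox` model.
#' @param newdata Cohort tibble covering the selected predictors.
#' @param ... Unused.
#' @return Numeric vector of event probabilities in \[0, 1\].
#' @export
predict.crp_cox <- function(object, newdata, ...) {
  X <- build_design(newdata, object$predictors, object$fp_specs)
  beta <- stats::setNames(object$coefficients$estimate,
                          object$coefficients$term)
  if (!all(names(beta) %in% colnames(X)))
    stop("newdata lacks levels/terms required by the model", call. = FALSE)
  lp <- drop(X[, names(beta), drop = FALSE] %*% beta) -
    sum(object$centers[names(beta)] * beta)
  1 - object$s0^exp(lp)
}

#' @export
print.crp_cox <- function(x, ...) {
  cat("<crp_cox> ", length(x$predictors), "predictors; S0(",
      x$horizon, "y) =", format(x$s0, digits = 4), "\n")
  invisible(x)
}

#' Full pseudovalue cloglog model across imputations
#'
#' Regresses jackknife pseudovalues of the cause-1 cumulative incidence at
#' the horizon on all candidate predictors in a generalised linear model
#' with complementary log-log link and constant-variance quasi-likelihood,
#' with robust (HC0 sandwich) standard errors for the non-independence of
#' pseudovalues. Per-imputation fits are Rubin-pooled. The resulting
#' coefficients are on the subdistribution (Fine-Gray) scale.
#'
#' @inheritParams fit_cox_full
#' @param pseudo Numeric vector of pseudovalues aligned with the cohort
#'   rows (identical across imputations, since follow-up is fully
#'   observed).
#' @return A `crp_pooled_coefs` table including the intercept row.
#' @export
fit_pseudo_cloglog_full <- function(stack, pseudo,
                                    predictors = candidate_predictors(),
                                    fp_specs = list()) {
  datasets <- imputation_list(stack)
  fits <- lapply(datasets, function(d) {
    X <- build_design(d, predictors, fp_specs)
    glm_fit_robust(pseudo, X)
  })
  pool_coef_table(fits, intercept = TRUE)
}

glm_fit_robust <- function(pseudo, X) {
  fit <- fit_pseudo_glm(pseudo, X)
  if (!fit$converged) warning("pseudovalue cloglog GLM did not converge",
                              call. = FALSE)
  rv <- diag(sandwich::vcovHC(fit, type = "HC0"))
  nm <- c("(Intercept)", colnames(X))
  list(coef = stats::setNames(stats::coef(fit), nm),
       var = stats::setNames(rv, nm), X = X)
}

#' Fit the final pseudovalue cloglog model
#'
#' @inheritParams fit_pseudo_cloglog_full
#' @param predictors Selected predictors (from [select_predictors()] applied
#'   to the full pseudovalue model).
#' @param horizon Horizon the pseudovalues refer to (metadata).
#' @return A `crp_cloglog` model object.
#' @export
fit_pseudo_cloglog <- function(stack, pseudo, predictors, fp_specs = list(),
                               horizon = 10) {
  if (length(predictors) == 0) stop("empty predictor list", call. = FALSE)
  if (stats::var(pseudo) < 1e-12)
    stop("degenerate input: all pseudovalues equal", call. = FALSE)
  datasets <- imputation_list(stack)
  fits <- lapply(datasets, function(d) {
    X <- build_design(d, predictors, fp_specs)
    glm_fit_robust(pseudo, X)
  })
  pooled <- pool_coef_table(fits, intercept = TRUE)
  structure(list(coefficients = pooled, predictors = predictors,
                 fp_specs = fp_specs, horizon = horizon),
            class = "crp_cloglog")
}

#' Predicted event probability from the pseudovalue cloglog model
#'
#' risk = 1 - exp(-exp(lp)) with lp the linear predictor including the
#' intercept; values lie in (0, 1) and are monotone in lp.
#'
#' @param object A `crp_cloglog` model.
#' @param newdata Cohort tibble covering the predictors.
#' @param ... Unused.
#' @return Numeric vector of event probabilities.
#' @export
predict.crp_cloglog <- function(object, newdata, ...) {
  X <- build_design(newdata, object$predictors, object$fp_specs)
  cf <- object$coefficients
  beta <- stats::setNames(cf$estimate, cf$term)
  terms <- setdiff(names(beta), "(Intercept)")
  if (!all(terms %in% colnames(X)))
    stop("newdata lacks levels/terms required by the model", call. = FALSE)
  lp <- beta[["(Intercept)"]] + drop(X[, terms, drop = FALSE] %*% beta[terms])
  1 - exp(-exp(lp))
}

#' @export
print.crp_cloglog <- function(x, ...) {
  cat("<crp_cloglog> ", length(x$predictors), "predictors at horizon",
      x$horizon, "y\n")
  invisible(x)
}

#' Events per candidate predictor parameter
#'
#' @param events Number of events.
#' @param n_parameters Number of predictor parameters (> 0).
#' @return events / n_parameters.
#' @export
events_per_parameter <- function(events, n_parameters) {
  if (n_parameters <= 0) stop("`n_parameters` must be > 0", call. = FALSE)
  events / n_parameters
}
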