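#' Chained-equations multiple imputation for cohort tables
#'
#' Multiple imputation by chained equations tailored to the cohort layout:
#' each incomplete covariate is imputed conditional on all other candidate
#' predictors, the endpoint indicator (cause code as a factor), the
#' Nelson-Aalen cumulative hazard evaluated at the subject's follow-up time,
#' the period of cohort entry, and region. BMI is imputed on the natural log
#' scale and exponentiated back.
#'
#' Conditional models: predictive mean matching (k = 5 donors, with a
#' Bayesian draw of the regression coefficients) for continuous variables,
#' Bayesian logistic regression for binaries, multinomial logistic
#' (via \pkg{nnet}) for unordered categoricals and proportional odds (via
#' \pkg{MASS}) for the ordered stage, both drawing imputations from the
#' fitted class probabilities.
#'
#' @param data Cohort tibble (columns `time`, `cause`, `period`, `region`
#'   plus covariates; `NA` marks missingness).
#' @param vars Character vector of variables to impute; defaults to all
#'   covariates with any missing values.
#' @param m Number of imputations (>= 2; default 5).
#' @param n_cycles Chained-equation cycles per imputation (default 10).
#' @param seed Integer seed.
#' @param max_fit_n Per-model cap on rows used to estimate each conditional
#'   model (a random subset of responders; imputations are still drawn for
#'   every missing row). Keeps large-cohort runs fast.
#' @return An object of class `crp_imputation_stack`: list with
#'   `imputations` (list of m completed tibbles), `m`, `vars`, `seed`.
#' @export
impute_chained <- function(data, vars = NULL, m = 5, n_cycles = 10, seed = 1L,
                           max_fit_n = 10000L) {
  if (m < 2) stop("`m` must be >= 2", call. = FALSE)
  candidate <- setdiff(names(data), c("id", "entry", "time", "cause", "truth",
                                      grep("^\\.", names(data), value = TRUE)))
  if (is.null(vars)) vars <- candidate[vapply(data[candidate], anyNA, TRUE)]
  if (length(vars) > 0 && any(colMeans(is.na(data[vars])) == 1))
    stop("variable with 100% missingness cannot be imputed", call. = FALSE)
  if (!any(!vapply(data[candidate], anyNA, TRUE)))
    stop("at least one fully observed variable is required", call. = FALSE)

  # auxiliary variables: endpoint indicator, Nelson-Aalen value, period, region
  na_est <- nelson_aalen(data$time, as.integer(data$cause != 0))
  aux <- tibble::tibble(
    .cause_f = factor(data$cause),
    .na_cumhaz = step_eval(na_est, data$time),
    .period_f = factor(data$period),
    .region_f = factor(data$region)
  )
  work <- dplyr::bind_cols(data[candidate], aux)
  if ("bmi" %in% names(work)) work$bmi <- log(work$bmi)

  miss <- lapply(work[vars], is.na)
  vars <- vars[order(vapply(miss[vars], sum, 0L))]

  set.seed(seed)
  imputations <- vector("list", m)
  for (k in seq_len(m)) {
    cur <- work
    for (v in vars) cur[[v]][miss[[v]]] <- sample(cur[[v]][!miss[[v]]],
                                                  sum(miss[[v]]), replace = TRUE)
    for (cyc in seq_len(if (length(vars)) n_cycles else 0L)) {
      for (v in vars) {
        cur[[v]][miss[[v]]] <- draw_imputation(cur, v, miss[[v]], max_fit_n)
      }
    }
    out <- data
    for (v in vars) {
      val <- cur[[v]]
      if (v == "bmi") val <- exp(val)
      out[[v]] <- val
    }
    imputations[[k]] <- out
  }
  structure(list(imputations = imputations, m = m, vars = vars, seed = seed),
            class = "crp_imputation_stack")
}

# One chained-equation update: fit the conditional model for `v` on observed
# rows of the current completed data and draw imputations for missing rows.
draw_imputation <- function(cur, v, is_miss, max_fit_n) {
  rhs <- setdiff(names(cur), v)
  X <- stats::model.matrix(~ ., data = cur[rhs])
  y <- cur[[v]]
  obs_idx <- which(!is_miss)
  fit_idx <- if (length(obs_idx) > max_fit_n) sample(obs_idx, max_fit_n) else obs_idx
  qrf <- qr(X[fit_idx, , drop = FALSE])
  keep <- qrf$pivot[seq_len(qrf$rank)]
  Xf <- X[fit_idx, keep, drop = FALSE]
  Xm <- X[is_miss, keep, drop = FALSE]

  if (is.numeric(y) && !all(y %in% c(0, 1))) {
    return(pmm_draw(Xf, y[fit_idx], Xm, X[obs_idx, keep, drop = FALSE], y[obs_idx]))
  }
  if (is.numeric(y)) {                       # binary 0/1: Bayesian logistic
    fit <- suppressWarnings(stats::glm.fit(Xf, y[fit_idx],
                                           family = stats::binomial()))
    beta <- fit$coefficients
    cov <- tryCatch(chol2inv(chol(crossprod(Xf * sqrt(fit$weights)))),
                    error = function(e) diag(1e-8, length(beta)))
    beta_dot <- beta + drop(stats::rnorm(length(beta)) %*% chol(cov + diag(1e-10, nrow(cov))))
    p <- stats::plogis(drop(Xm %*% beta_dot))
    return(stats::rbinom(nrow(Xm), 1, p))
  }

  # categorical: intercept-free predictor frames (polr/multinom add their own)
  cols <- setdiff(colnames(Xf), "(Intercept)")
  dff <- data.frame(y = y[fit_idx], Xf[, cols, drop = FALSE], check.names = TRUE)
  dfm <- data.frame(Xm[, cols, drop = FALSE], check.names = TRUE)
  names(dfm) <- names(dff)[-1]
  fit <- if (is.ordered(y)) {
    tryCatch(suppressWarnings(MASS::polr(y ~ ., data = dff, Hess = FALSE)),
             error = function(e) NULL)
  } else {
    tryCatch(nnet::multinom(y ~ ., data = dff, trace = FALSE, maxit = 60,
                            MaxNWts = 5000),
             error = function(e) NULL)
  }
  draw_from_probs(fit, dfm, y, is_miss)
}

# Predictive mean matching with Bayesian parameter draw and k = 5 donors.
pmm_draw <- function(Xf, yf, Xm, Xobs, yobs, k_donors = 5L) {
  qrf <- qr(Xf)
  beta <- qr.coef(qrf, yf)
  res <- yf - drop(Xf %*% beta)
  df <- max(length(yf) - ncol(Xf), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrf)
  beta_dot <- beta + drop(backsolve(R, stats::rnorm(ncol(Xf)))) * sqrt(sigma2)
  pred_obs <- drop(Xobs %*% beta)
  pred_mis <- drop(Xm %*% beta_dot)
  vapply(pred_mis, function(p) {
    donors <- order(abs(pred_obs - p))[seq_len(min(k_donors, length(pred_obs)))]
    yobs[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

# Draw categorical imputations from fitted class probabilities; falls back to
# the observed marginal when the conditional fit failed.
draw_from_probs <- function(fit, newdata, y, is_miss) {
  lev <- levels(y)
  if (is.null(fit)) {
    return(sample(y[!is_miss], sum(is_miss), replace = TRUE))
  }
  pr <- stats::predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)   # two-level case
  pr <- pmin(pmax(pr, 0), 1)
  drawn <- apply(pr, 1, function(p) sample(lev, 1L, prob = p + 1e-12))
  factor(drawn, levels = lev, ordered = is.ordered(y))
}

#' Stack imputed datasets into one long table
#'
#' @param stack A `crp_imputation_stack`.
#' @return Tibble with m x n rows and an `.imp` index column; filtering on
#'   `.imp` recovers each completed dataset.
#' @export
stack_imputations <- function(stack) {
  stopifnot(inherits(stack, "crp_imputation_stack"))
  dplyr::bind_rows(stack$imputations, .id = ".imp") |>
    dplyr::mutate(.imp = as.integer(.data$.imp)) |>
    dplyr::relocate(".imp")
}

#' @export
print.crp_imputation_stack <- function(x, ...) {
  cat("<crp_imputation_stack> m =", x$m, "imputations of",
    nrow(x$imputations[[1]]), "rows; imputed:",
    paste(x$vars, collapse = ", "), "\n")
  invisible(x)
}

#' Rubin's rules for pooling across imputations
#'
#' Pools m point estimates and their variances: pooled estimate is the mean,
#' total variance T = W + (1 + 1/m) B with W the mean within-imputation
#' variance and B the between-imputation variance, and Barnard-Rubin
#' small-sample degrees of freedom.
#'
#' @param estimates Numeric vector of m per-imputation estimates (or a
#'   matrix with one column per parameter).
#' @param variances Matching vector/matrix of per-imputation variances
#'   (>= 0).
#' @param df_com Complete-data degrees of freedom (default `Inf`, giving the
#'   classical large-sample df).
#' @return Tibble with columns `estimate`, `within`, `between`, `total`,
#'   `se`, `df` (one row per parameter).
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf) {
  est <- as.matrix(estimates); var <- as.matrix(variances)
  m <- nrow(est)
  if (m < 2) stop("Rubin's rules require m >= 2", call. = FALSE)
  if (any(var < 0, na.rm = TRUE)) stop("variances must be >= 0", call. = FALSE)
  qbar <- colMeans(est)
  w <- colMeans(var)
  b <- apply(est, 2, stats::var)
  tt <- w + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / tt
  lambda <- pmin(pmax(lambda, 1e-12), 1 - 1e-12)
  df_old <- (m - 1) / lambda^2
  df <- if (is.finite(df_com)) {
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    1 / (1 / df_old + 1 / df_obs)
  } else df_old
  tibble::tibble(term = colnames(est) %||% as.character(seq_along(qbar)),
                 estimate = qbar, within = w, between = b, total = tt,
                 se = sqrt(tt), df = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
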