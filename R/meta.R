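#' Hartung-Knapp-Sidik-Jonkman random-effects meta-analysis
#'
#' Pools cluster-level performance estimates with DerSimonian-Laird tau^2
#' and the Hartung-Knapp-Sidik-Jonkman variance adjustment: the pooled
#' variance is q / sum(w*) with q = sum(w* (y - pooled)^2) / (k - 1) and
#' w* = 1 / (se^2 + tau^2), and the confidence interval uses a
#' t-distribution with k - 1 degrees of freedom. The 95% prediction
#' interval, pooled +/- t_{k-2} * sqrt(tau^2 + se_pooled^2), estimates the
#' performance range expected in a new cluster and requires k >= 3.
#'
#' @param estimates Numeric vector of k cluster estimates (k >= 2).
#' @param ses Matching positive standard errors.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble of class `crp_meta`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pi_low`, `pi_high`, `tau2`, `i2`, `k`.
#' @export
hksj_random_effects <- function(estimates, ses, conf_level = 0.95) {
  k <- length(estimates)
  if (k < 2) stop("need at least 2 clusters", call. = FALSE)
  if (length(ses) != k || any(ses <= 0))
    stop("`ses` must be positive and match `estimates`", call. = FALSE)
  w <- 1 / ses^2
  ybar <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - ybar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / cc)
  i2 <- max(0, (q - (k - 1)) / q) * 100
  ws <- 1 / (ses^2 + tau2)
  pooled <- sum(ws * estimates) / sum(ws)
  qh <- sum(ws * (estimates - pooled)^2) / (k - 1)
  se_p <- sqrt(qh / sum(ws))
  a <- 1 - (1 - conf_level) / 2
  ci_half <- stats::qt(a, df = k - 1) * se_p
  if (k >= 3) {
    pi_half <- stats::qt(a, df = k - 2) * sqrt(tau2 + se_p^2)
    pi_low <- pooled - pi_half; pi_high <- pooled + pi_half
  } else {
    pi_low <- NA_real_; pi_high <- NA_real_
  }
  out <- tibble::tibble(estimate = pooled, se = se_p,
                        ci_low = pooled - ci_half, ci_high = pooled + ci_half,
                        pi_low = pi_low, pi_high = pi_high,
                        tau2 = tau2, i2 = i2, k = k)
  class(out) <- c("crp_meta", class(out))
  out
}

#' Random-effects meta-regression with heterogeneity decomposition
#'
#' Weighted meta-regression of cluster estimates on cluster-level
#' covariates with a moment-based residual tau^2 (the DerSimonian-Laird
#' generalisation), HKSJ-scaled coefficient standard errors, residual I^2
#' from the residual Q statistic, and R^2 = max(0, 100 * (1 -
#' tau2_model / tau2_null)) — the share of between-cluster heterogeneity
#' attributable to the covariates, clipped to [0, 100].
#'
#' @param estimates,ses Cluster estimates and positive standard errors.
#' @param covariates Data frame / matrix of cluster-level covariates
#'   (k rows; an intercept is added).
#' @return List of class `crp_metareg`: `coefficients` tibble, `tau2`,
#'   `tau2_null`, `r2`, `i2_residual`, `k`.
#' @export
meta_regression <- function(estimates, ses, covariates) {
  k <- length(estimates)
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  p <- ncol(X)
  if (k <= p + 1) stop("need k > number of covariates + 2 clusters", call. = FALSE)
  if (qr(X)$rank < p) stop("collinear covariates", call. = FALSE)

  tau2_null <- hksj_random_effects(estimates, ses)$tau2

  w <- 1 / ses^2
  WX <- X * w
  xtwx_inv <- solve(crossprod(X, WX))
  beta_fe <- drop(xtwx_inv %*% crossprod(WX, estimates))
  resid_fe <- estimates - drop(X %*% beta_fe)
  q_res <- sum(w * resid_fe^2)
  # tr(P) for the moment estimator: sum(w) - tr((X'WX)^{-1} X'W^2X)
  tr_p <- sum(w) - sum(diag(xtwx_inv %*% crossprod(X * w, WX)))
  tau2 <- max(0, (q_res - (k - p)) / tr_p)
  i2_res <- max(0, (q_res - (k - p)) / q_res) * 100

  ws <- 1 / (ses^2 + tau2)
  WXs <- X * ws
  vcov0 <- solve(crossprod(X, WXs))
  beta <- drop(vcov0 %*% crossprod(WXs, estimates))
  resid <- estimates - drop(X %*% beta)
  qh <- sum(ws * resid^2) / (k - p)          # HKSJ scaling
  vcov_h <- qh * vcov0
  se <- unname(sqrt(diag(vcov_h)))
  beta <- unname(beta)
  coefs <- tibble::tibble(term = colnames(X), estimate = beta, se = se,
                          df = k - p,
                          p = 2 * stats::pt(abs(beta / se), df = k - p,
                                            lower.tail = FALSE))
  r2 <- if (tau2_null <= 0) 0 else max(0, 100 * (1 - tau2 / tau2_null))
  structure(list(coefficients = coefs, tau2 = tau2, tau2_null = tau2_null,
                 r2 = min(r2, 100), i2_residual = i2_res, k = k),
            class = "crp_metareg")
}

#' @export
print.crp_metareg <- function(x, ...) {
  cat("<crp_metareg> k =", x$k, " R2 =", format(x$r2, digits = 4),
      "% residual I2 =", format(x$i2_residual, digits = 4), "%\n")
  print(x$coefficients)
  invisible(x)
}

#' Rubin-pool per-imputation cluster metrics
#'
#' Applies Rubin's rules to a long table of per-imputation,
#' per-cluster metric estimates before meta-analysis.
#'
#' @param metrics Tibble with columns `region`, `metric`, `.imp`, `value`,
#'   `se` (one row per cluster x metric x imputation).
#' @return Tibble with one row per cluster x metric: pooled `value`, `se`.
#' @export
pool_metric_over_imputations <- function(metrics) {
  stopifnot(all(c("region", "metric", ".imp", "value", "se") %in% names(metrics)))
  metrics |>
    dplyr::group_by(.data$region, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      d <- d[is.finite(d$value) & is.finite(d$se), ]
      if (nrow(d) == 0)
        return(tibble::tibble(value = NA_real_, se = NA_real_, m = 0L))
      if (nrow(d) == 1)
        return(tibble::tibble(value = d$value, se = d$se, m = 1L))
      p <- rubin_pool(d$value, d$se^2)
      tibble::tibble(value = p$estimate, se = p$se, m = nrow(d))
    }) |>
    dplyr::ungroup()
}
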