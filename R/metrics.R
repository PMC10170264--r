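#' Crude event rate with log-scale confidence interval
#'
#' rate = scale * events / person_years, with the 95% CI computed on the
#' log scale as rate * exp(+/- z / sqrt(events)). With zero events the rate
#' is 0 and the CI is flagged undefined. The log-symmetric construction
#' implies ci_low * ci_high = rate^2 exactly.
#'
#' @param events Event count (>= 0).
#' @param person_years Total person-time (> 0).
#' @param scale Denominator scale (default 10 000 person-years).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `events`, `person_years`, `rate`, `ci_low`,
#'   `ci_high`, `ci_defined`.
#' @export
crude_rate <- function(events, person_years, scale = 10000,
                       conf_level = 0.95) {
  if (person_years <= 0) stop("`person_years` must be > 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rate <- scale * events / person_years
  if (events == 0) {
    return(tibble::tibble(events = events, person_years = person_years,
                          rate = 0, ci_low = NA_real_, ci_high = NA_real_,
                          ci_defined = FALSE))
  }
  half <- z / sqrt(events)
  tibble::tibble(events = events, person_years = person_years, rate = rate,
                 ci_low = rate * exp(-half), ci_high = rate * exp(half),
                 ci_defined = TRUE)
}

# Left-limit evaluation of a step estimate (value just before t).
step_eval_left <- function(est, t) {
  base <- if (attr(est, "kind") %in% c("survival", "censoring_survival")) 1 else 0
  if (nrow(est) == 0L) return(rep(base, length(t)))
  idx <- findInterval(t, est$time, left.open = TRUE)
  c(base, est$estimate)[idx + 1L]
}

#' Harrell's C index at a horizon
#'
#' Concordance over usable pairs after administrative truncation at the
#' horizon (times beyond the horizon are censored there): the member of a
#' pair with the shorter time must have an observed event, ties in
#' predicted risk count one half. Computed via [survival::concordance()]
#' (higher risk should predict shorter time), with its pair-based standard
#' error.
#'
#' @param time Follow-up times.
#' @param event Event indicator at face value (0/1); for competing-risks
#'   data pass `cause == 1`.
#' @param risk Predicted event probabilities (higher = worse prognosis).
#' @param horizon Truncation horizon in years.
#' @return One-row tibble: `metric = "harrell_c"`, `value`, `se`.
#' @export
harrells_c <- function(time, event, risk, horizon = 10) {
  stopifnot(all(is.finite(risk)))
  e <- as.integer(event != 0 & time <= horizon)
  tt <- pmin(time, horizon)
  cf <- survival::concordance(survival::Surv(tt, e) ~ risk, reverse = TRUE)
  if (sum(cf$count[1:3]) == 0) stop("no usable pairs", call. = FALSE)
  tibble::tibble(metric = "harrell_c", value = cf$concordance,
                 se = sqrt(cf$var))
}

#' IPCW concordance for competing-risks predictions
#'
#' Truncated concordance with inverse probability of censoring weighting:
#' cases are subjects failing from the cause of interest by the horizon;
#' for case i, comparators are subjects still event-free at t_i
#' (weight 1 / G(t_i-)^2) and subjects who failed earlier from the
#' competing cause (weight 1 / (G(t_i-) G(t_j-))), where G is the
#' Kaplan-Meier censoring-survival estimate. Concordant pairs have
#' risk_i > risk_j; risk ties count one half. Pairs whose weight is
#' undefined because G has reached zero are dropped with a warning. The
#' standard error is a case-clustered linearisation (between-case
#' variability of per-case concordance).
#'
#' @param time,cause Follow-up and cause codes (0/1/2).
#' @param risk Predicted event-of-interest probabilities.
#' @param horizon Truncation horizon.
#' @param cause_of_interest Cause defining cases (default 1).
#' @return One-row tibble: `metric = "ipcw_c"`, `value`, `se`.
#' @export
ipcw_c_index <- function(time, cause, risk, horizon = 10,
                         cause_of_interest = 1) {
  stopifnot(all(is.finite(risk)))
  G <- censoring_survival(time, cause)
  gi <- step_eval_left(G, pmin(time, horizon))
  cases <- which(cause == cause_of_interest & time <= horizon)
  if (length(cases) == 0) stop("no usable pairs: no cases by horizon", call. = FALSE)
  dropped <- FALSE
  num <- 0; den <- 0
  ci_num <- numeric(length(cases)); ci_den <- numeric(length(cases))
  for (k in seq_along(cases)) {
    i <- cases[k]
    conc <- (risk[i] > risk) + 0.5 * (risk[i] == risk)
    w <- numeric(length(time))
    riskset <- time > time[i]
    compet <- time <= time[i] & cause != cause_of_interest & cause != 0
    compet[i] <- FALSE
    if (gi[i] <= 0) { dropped <- dropped || any(riskset | compet); next }
    w[riskset] <- 1 / gi[i]^2
    ok <- compet & gi > 0
    dropped <- dropped || any(compet & gi <= 0)
    w[ok] <- 1 / (gi[i] * gi[ok])
    ci_num[k] <- sum(w * conc)
    ci_den[k] <- sum(w)
    num <- num + ci_num[k]; den <- den + ci_den[k]
  }
  if (dropped) warning("pairs with zero censoring-survival weight dropped",
                       call. = FALSE)
  if (den == 0) stop("no usable pairs", call. = FALSE)
  cval <- num / den
  se <- sqrt(sum((ci_num - cval * ci_den)^2)) / den
  tibble::tibble(metric = "ipcw_c", value = cval, se = se)
}

#' Calibration slope and calibration-in-the-large
#'
#' On the complementary log-log scale: the slope is the coefficient of a
#' quasi-likelihood GLM of pseudo-observations on cloglog(risk) with
#' cloglog link; calibration-in-the-large is the intercept of the same
#' family with cloglog(risk) as an offset. Robust (HC0) standard errors.
#' Ideal values are 1 and 0. Predictions are clipped away from exact 0/1
#' by `eps` before the link transform.
#'
#' @param pseudo Pseudo-observations (event indicators or jackknife
#'   pseudovalues of the relevant failure functional).
#' @param risk Predicted event probabilities.
#' @param eps Clipping bound (default 1e-6).
#' @return Two-row tibble: metrics `"slope"` and `"citl"` with `value`,
#'   `se`.
#' @export
calibration_slope_citl <- function(pseudo, risk, eps = 1e-6) {
  p <- pmin(pmax(risk, eps), 1 - eps)
  cll <- log(-log(1 - p))
  if (stats::var(cll) < 1e-12)
    stop("constant predictions: calibration slope undefined", call. = FALSE)
  mustart <- pmin(pmax(pseudo, 0.001), 0.999)
  fam <- stats::quasi(link = "cloglog", variance = "constant")
  fs <- stats::glm(pseudo ~ cll, family = fam, mustart = mustart,
                   control = stats::glm.control(maxit = 100))
  fc <- stats::glm(pseudo ~ 1 + offset(cll), family = fam, mustart = mustart,
                   control = stats::glm.control(maxit = 100))
  tibble::tibble(
    metric = c("slope", "citl"),
    value = c(stats::coef(fs)[["cll"]], stats::coef(fc)[["(Intercept)"]]),
    se = c(sqrt(sandwich::vcovHC(fs, type = "HC0")["cll", "cll"]),
           sqrt(sandwich::vcovHC(fc, type = "HC0")[1, 1])))
}

#' Calibration-in-the-large only (valid under constant predictions)
#' @inheritParams calibration_slope_citl
#' @return One-row tibble.
#' @export
calibration_citl <- function(pseudo, risk, eps = 1e-6) {
  p <- pmin(pmax(risk, eps), 1 - eps)
  cll <- log(-log(1 - p))
  mustart <- pmin(pmax(pseudo, 0.001), 0.999)
  fc <- stats::glm(pseudo ~ 1 + offset(cll),
                   family = stats::quasi(link = "cloglog", variance = "constant"),
                   mustart = mustart)
  tibble::tibble(metric = "citl", value = stats::coef(fc)[["(Intercept)"]],
                 se = sqrt(sandwich::vcovHC(fc, type = "HC0")[1, 1]))
}

#' Smoothed calibration curve from individual pseudovalues
#'
#' Running (lowess) smoother of observed individual pseudovalues against
#' predicted risks, evaluated on a grid; the distribution of predictions is
#' retained so plots can show the companion histogram.
#'
#' @param risk Predicted probabilities (n >= 50).
#' @param pseudo Pseudo-observations.
#' @param grid Evaluation grid (default: 100 points spanning the observed
#'   prediction range). Grid points outside the observed range are flagged
#'   as extrapolation.
#' @param f Lowess smoother span (default 0.3).
#' @return Tibble of class `crp_calibration_curve` with `predicted`,
#'   `observed`, `extrapolated`; the prediction vector is kept as an
#'   attribute for plotting.
#' @export
smoothed_calibration_curve <- function(risk, pseudo, grid = NULL, f = 0.3) {
  if (length(risk) < 50) stop("need n >= 50 for a smoothed curve", call. = FALSE)
  if (is.null(grid)) grid <- seq(min(risk), max(risk), length.out = 100)
  # iter = 0: robustness iterations would treat the two-point-mass shape of
  # pseudovalues (near 0, near 1 or beyond) as outliers and bias the curve
  sm <- stats::lowess(risk, pseudo, f = f, iter = 0)
  obs <- stats::approx(sm$x, sm$y, xout = grid, rule = 2, ties = mean)$y
  out <- tibble::tibble(predicted = grid, observed = obs,
                        extrapolated = grid < min(risk) | grid > max(risk))
  class(out) <- c("crp_calibration_curve", class(out))
  attr(out, "risk") <- risk
  out
}

#' Decision curve analysis at a horizon
#'
#' Net benefit NB(p_t) = P(risk >= p_t) * (F_high - (1 - F_high) * p_t /
#' (1 - p_t)), where F_high is the event probability by the horizon among
#' the high-risk group: the Aalen-Johansen CIF of the cause of interest
#' when `competing = TRUE` (competing deaths accounted for) and the
#' Kaplan-Meier failure probability (competing deaths censored) otherwise.
#' Treat-all uses the whole-sample F; treat-none is identically zero.
#'
#' @param time,cause Follow-up and cause codes.
#' @param risk Predicted probabilities.
#' @param horizon Horizon in years.
#' @param thresholds Threshold probabilities in (0, 1)
#'   (default 0.01-0.50 by 0.01).
#' @param competing Account for competing risks (default `TRUE`).
#' @return Tibble of class `crp_decision_curve`: `threshold`, `strategy`
#'   (`model` / `treat_all` / `treat_none`), `net_benefit`, `empty_group`.
#' @export
decision_curve <- function(time, cause, risk, horizon = 10,
                           thresholds = seq(0.01, 0.5, by = 0.01),
                           competing = TRUE) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  f_at <- function(idx) {
    if (competing) aj_cif_at(time[idx], cause[idx], horizon)
    else 1 - step_eval(km_survival(time[idx],
                                   as.integer(cause[idx] == 1)), horizon)
  }
  f_all <- f_at(seq_along(time))
  rows <- purrr::map_dfr(thresholds, function(pt) {
    odds <- pt / (1 - pt)
    high <- risk >= pt
    if (!any(high)) {
      nb_model <- 0; empty <- TRUE
    } else {
      fh <- f_at(which(high))
      nb_model <- mean(high) * (fh - (1 - fh) * odds)
      empty <- FALSE
    }
    tibble::tibble(
      threshold = pt,
      strategy = c("model", "treat_all", "treat_none"),
      net_benefit = c(nb_model, f_all - (1 - f_all) * odds, 0),
      empty_group = c(empty, FALSE, FALSE))
  })
  class(rows) <- c("crp_decision_curve", class(rows))
  attr(rows, "competing") <- competing
  rows
}

#' Performance metrics within subgroups
#'
#' Computes Harrell's C, calibration slope and calibration-in-the-large
#' within levels of a grouping variable (cancer stage, 10-year age band,
#' an ethnicity analogue) from pooled individual-level predictions.
#' Groups with fewer than two events are flagged not estimable.
#'
#' @param data Tibble with `time`, `cause`, a risk column and a `.pseudo`
#'   column.
#' @param group Grouping column name (string).
#' @param risk_col Name of the prediction column (default `".risk"`).
#' @param horizon Horizon in years.
#' @return Tibble: `group`, `level`, `metric`, `value`, `se`, `n`,
#'   `n_events`, `estimable`.
#' @export
subgroup_metrics <- function(data, group, risk_col = ".risk", horizon = 10) {
  stopifnot(group %in% names(data), risk_col %in% names(data),
            ".pseudo" %in% names(data))
  data |>
    dplyr::group_by(level = as.character(.data[[group]])) |>
    dplyr::group_modify(function(d, key) {
      ne <- sum(d$cause == 1 & d$time <= horizon)
      if (ne < 2) {
        return(tibble::tibble(metric = c("harrell_c", "slope", "citl"),
                              value = NA_real_, se = NA_real_, n = nrow(d),
                              n_events = ne, estimable = FALSE))
      }
      cc <- harrells_c(d$time, d$cause == 1, d[[risk_col]], horizon)
      cal <- tryCatch(calibration_slope_citl(d$.pseudo, d[[risk_col]]),
                      error = function(e)
                        tibble::tibble(metric = c("slope", "citl"),
                                       value = NA_real_, se = NA_real_))
      dplyr::bind_rows(cc, cal) |>
        dplyr::mutate(n = nrow(d), n_events = ne, estimable = TRUE)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = group, .before = 1)
}
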