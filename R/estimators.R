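#' Step-function estimates of survival quantities
#'
#' Internal constructor for right-continuous piecewise-constant estimates
#' (survival, cumulative incidence, censoring survival, cumulative hazard).
#'
#' @param times Sorted distinct event times (years).
#' @param values Estimate immediately after each time.
#' @param kind One of `"survival"`, `"cif"`, `"censoring_survival"`, `"cumhaz"`.
#' @return A tibble of class `crp_step` with columns `time` and `estimate`.
#' @keywords internal
new_step_estimate <- function(times, values, kind) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  out <- tibble::tibble(time = as.numeric(times), estimate = as.numeric(values))
  class(out) <- c("crp_step", class(out))
  attr(out, "kind") <- kind
  out
}

#' Evaluate a step estimate at arbitrary times
#'
#' Right-continuous evaluation: queries between jumps return the value at the
#' preceding jump; queries before the first jump return the baseline (1 for
#' survival-type curves, 0 for CIF and cumulative hazard); queries beyond the
#' last jump carry the last value forward.
#'
#' @param est A `crp_step` object.
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector of estimates at `t`.
#' @export
step_eval <- function(est, t) {
  stopifnot(inherits(est, "crp_step"))
  base <- if (attr(est, "kind") %in% c("survival", "censoring_survival")) 1 else 0
  if (nrow(est) == 0L) return(rep(base, length(t)))
  idx <- findInterval(t, est$time)
  c(base, est$estimate)[idx + 1L]
}

#' @export
print.crp_step <- function(x, ...) {
  cat("<crp_step> kind:", attr(x, "kind"), "with", nrow(x), "jump(s)\n")
  NextMethod()
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function, treating any non-zero
#' cause code as the event. At tied times, events are processed before
#' censorings (both remain in the risk set at that time).
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (0 = censored; non-zero = event).
#' @return A `crp_step` estimate of kind `"survival"`.
#' @export
km_survival <- function(time, event) {
  check_time_event(time, event)
  fit <- survival::survfit(survival::Surv(time, event != 0) ~ 1)
  new_step_estimate(fit$time, fit$surv, "survival")
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' The censoring-survival function G(t), estimated by the product-limit
#' method with censoring (cause 0) treated as the event and all failures
#' (any non-zero cause) treated as censored. G is the ingredient of inverse
#' probability of censoring weights.
#'
#' @param time Follow-up times (> 0).
#' @param cause Cause codes: 0 censored, 1 event of interest, 2 competing.
#' @return A `crp_step` estimate of kind `"censoring_survival"`.
#' @export
censoring_survival <- function(time, cause) {
  check_time_event(time, cause)
  fit <- survival::survfit(survival::Surv(time, cause == 0) ~ 1)
  new_step_estimate(fit$time, fit$surv, "censoring_survival")
}

#' Nelson-Aalen cumulative hazard estimate
#'
#' H(t) = sum over event times of d_j / n_j. The per-subject evaluation
#' H(time_i) is the standard auxiliary variable for imputation models with
#' survival outcomes.
#'
#' @inheritParams km_survival
#' @return A `crp_step` estimate of kind `"cumhaz"`.
#' @export
nelson_aalen <- function(time, event) {
  check_time_event(time, event)
  cnt <- event_counts(time, as.integer(event != 0))
  new_step_estimate(cnt$time, cumsum(cnt$d1 / cnt$n_risk), "cumhaz")
}

#' Aalen-Johansen cumulative incidence function
#'
#' Nonparametric CIF for one cause in the presence of competing events:
#' CIF_k(t) = sum over event times t_j <= t of S(t_j-) d_kj / n_j, where S is
#' the all-cause Kaplan-Meier survival. At tied times events precede
#' censorings.
#'
#' @param time Follow-up times (> 0).
#' @param cause Cause codes: 0 censored, positive integers for causes.
#' @param cause_of_interest Cause whose incidence is estimated (default 1).
#'   A cause absent from the data yields the zero function.
#' @return A `crp_step` estimate of kind `"cif"`.
#' @export
aalen_johansen <- function(time, cause, cause_of_interest = 1) {
  check_time_event(time, cause)
  cnt <- event_counts(time, cause, cause_of_interest)
  h_all <- cnt$dall / cnt$n_risk
  h1 <- cnt$d1 / cnt$n_risk
  s_minus <- c(1, cumprod(1 - h_all))[seq_along(h1)]
  new_step_estimate(cnt$time, cumsum(s_minus * h1), "cif")
}

#' Aalen-Johansen CIF at a single horizon
#'
#' @inheritParams aalen_johansen
#' @param horizon Evaluation time (> 0).
#' @return A single probability in \[0, 1\].
#' @export
aj_cif_at <- function(time, cause, horizon, cause_of_interest = 1) {
  stopifnot(horizon > 0)
  step_eval(aalen_johansen(time, cause, cause_of_interest), horizon)
}

# Distinct-time counting-process summary. `cause_of_interest` selects which
# cause feeds d1; `dall` counts all-cause events (any positive cause).
event_counts <- function(time, cause, cause_of_interest = 1) {
  ut <- sort(unique(time))
  j <- match(time, ut)
  d1 <- tabulate(j[cause == cause_of_interest], nbins = length(ut))
  dall <- tabulate(j[cause != 0], nbins = length(ut))
  total <- tabulate(j, nbins = length(ut))
  n_risk <- length(time) - c(0, cumsum(total))[seq_along(ut)]
  list(time = ut, d1 = d1, dall = dall, total = total, n_risk = n_risk, index = j)
}

check_time_event <- function(time, event) {
  if (length(time) == 0L) stop("empty input: no observations", call. = FALSE)
  if (length(time) != length(event)) stop("`time` and `event` lengths differ", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) stop("follow-up times must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

#' Jackknife pseudo-observations at a horizon
#'
#' Computes exact leave-one-out jackknife pseudovalues
#' theta_i = n * theta_hat - (n - 1) * theta_hat_(-i), where theta_hat is
#' either the Aalen-Johansen cumulative incidence of the cause of interest
#' (`target = "cif_cause1"`) or the Kaplan-Meier failure probability with
#' competing events treated as censored (`target = "km_failure"`), evaluated
#' at `horizon`.
#'
#' The implementation uses prefix products and a backward hazard recursion so
#' that all n leave-one-out estimates are obtained in O(n log n) total; it is
#' exactly equal (to numerical round-off) to recomputing the estimator n
#' times with one subject deleted.
#'
#' With censoring, pseudovalues may fall outside \[0, 1\]; the returned
#' object records their range for downstream clipping diagnostics.
#'
#' @param time Follow-up times (> 0), length >= 2.
#' @param cause Cause codes 0/1/2 (0 = censored).
#' @param horizon Evaluation time (> 0).
#' @param target `"cif_cause1"` (Aalen-Johansen CIF, default) or
#'   `"km_failure"` (1 - Kaplan-Meier, cause 2 censored).
#' @param cause_of_interest Cause defining the event of interest (default 1).
#' @return An object of class `crp_pseudo`: a list with `values` (one
#'   pseudovalue per subject, input order), `full_sample_estimate`,
#'   `horizon`, `target`, and `range`.
#' @export
pseudo_values <- function(time, cause, horizon,
                          target = c("cif_cause1", "km_failure"),
                          cause_of_interest = 1) {
  target <- match.arg(target)
  check_time_event(time, cause)
  n <- length(time)
  if (n < 2L) stop("pseudovalues require n >= 2", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)

  cause <- as.integer(cause)
  if (target == "km_failure") {
    # competing events act as censorings: only cause 1 feeds both d1 and dall
    cnt <- event_counts(time, as.integer(cause == cause_of_interest), 1L)
    d1flag <- as.integer(cause == cause_of_interest)
    delta <- d1flag
  } else {
    cnt <- event_counts(time, cause, cause_of_interest)
    d1flag <- as.integer(cause == cause_of_interest)
    delta <- as.integer(cause != 0L)
  }

  js <- findInterval(horizon, cnt$time)   # last index with t_j <= horizon
  if (js == 0L) {
    theta <- 0
    pv <- rep(0, n)
    out <- list(values = pv, full_sample_estimate = theta, horizon = horizon,
                target = target, range = range(pv))
    class(out) <- "crp_pseudo"
    return(out)
  }

  sel <- seq_len(js)
  d1 <- cnt$d1[sel]; dall <- cnt$dall[sel]; nr <- cnt$n_risk[sel]

  # full-sample estimate
  h1 <- d1 / nr
  h <- dall / nr
  s_minus <- c(1, cumprod(1 - h))[sel]
  incr <- s_minus * h1
  theta <- sum(incr)

  # "minus one at risk" regime: denominators n_j - 1 (safe-divide -> 0)
  nr1 <- nr - 1
  h1m <- ifelse(nr1 > 0, d1 / nr1, 0)
  hm <- ifelse(nr1 > 0, dall / nr1, 0)
  pm <- cumprod(1 - hm)                    # Pm_j
  pm_minus <- c(1, pm)[sel]                # Pm_{j-1}
  cm <- cumsum(pm_minus * h1m)             # Cm_j
  cm_minus <- c(0, cm)[sel]                # Cm_{j-1}

  # backward tail in the original ("plus") regime:
  # T_j = sum_{l > j} prod_{j < u < l} (1 - h_u) * h1_l, j = 1..js (T_js = 0)
  tail_t <- numeric(js)
  if (js > 1L) {
    acc <- 0
    for (j in seq(js - 1L, 1L)) {
      acc <- h1[j + 1L] + (1 - h[j + 1L]) * acc
      tail_t[j] <- acc
    }
  }

  r <- cnt$index                           # distinct-time index per subject
  loo <- numeric(n)
  beyond <- r > js
  loo[beyond] <- cm[js]

  within <- !beyond
  rw <- r[within]
  as_censored <- within & delta == 0L
  if (any(as_censored)) {
    ra <- r[as_censored]
    loo[as_censored] <- cm[ra] + pm[ra] * tail_t[ra]
  }
  as_event <- within & delta == 1L
  if (any(as_event)) {
    ra <- r[as_event]
    nra <- nr[ra]
    single <- nra == 1L
    h1a <- ifelse(single, 0, (d1[ra] - d1flag[as_event]) / (nra - 1))
    ha <- ifelse(single, 0, (dall[ra] - 1) / (nra - 1))
    val <- cm_minus[ra] + pm_minus[ra] * h1a +
      pm_minus[ra] * (1 - ha) * ifelse(single, 0, tail_t[ra])
    val[single] <- cm_minus[ra][single]
    loo[as_event] <- val
  }

  pv <- n * theta - (n - 1) * loo
  out <- list(values = pv, full_sample_estimate = theta, horizon = horizon,
              target = target, range = range(pv))
  class(out) <- "crp_pseudo"
  out
}

#' @export
print.crp_pseudo <- function(x, ...) {
  cat("<crp_pseudo>", x$target, "at horizon", x$horizon, "\n")
  cat("  n =", length(x$values),
      " full-sample estimate =", format(x$full_sample_estimate, digits = 5),
      " range = [", format(x$range[1], digits = 4), ",",
      format(x$range[2], digits = 4), "]\n")
  invisible(x)
}

#' Attach pseudo-observations to a cohort table
#'
#' Data-frame verb: computes jackknife pseudovalues (optionally within
#' strata, as required when fitting and evaluation use temporally distinct
#' data) and returns the cohort with a new `.pseudo` column.
#'
#' @param data Cohort tibble with `time` and `cause` columns.
#' @param horizon Evaluation horizon in years.
#' @param target Passed to [pseudo_values()].
#' @param by Optional column name (string) defining strata within which
#'   pseudovalues are computed separately.
#' @return `data` with an added numeric `.pseudo` column.
#' @export
add_pseudo_values <- function(data, horizon, target = c("cif_cause1", "km_failure"),
                              by = NULL) {
  target <- match.arg(target)
  stopifnot(all(c("time", "cause") %in% names(data)))
  if (is.null(by)) {
    data$.pseudo <- pseudo_values(data$time, data$cause, horizon, target)$values
    return(data)
  }
  stopifnot(by %in% names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      d$.pseudo <- pseudo_values(d$time, d$cause, horizon, target)$values
      d
    }) |>
    dplyr::ungroup()
}
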