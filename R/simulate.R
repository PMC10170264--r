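#' Simulation configuration for synthetic competing-risks cohorts
#'
#' Bundles the ground-truth parameters of the synthetic cohort generator.
#' The event of interest follows a Fine-Gray mixture: conditional on
#' covariates X and cluster effects, the probability of ever failing from
#' cause 1 is 1 - (1 - p_base)^exp(lp), with conditional failure times drawn
#' by inverse transform of the subdistribution
#' F1(t) = 1 - (1 - p_base * (1 - exp(-event_time_rate * t)))^exp(lp).
#' Competing events (cause 2) have an exponential hazard with its own linear
#' predictor. Censoring is exponential and independent of covariates, with
#' administrative censoring at the horizon.
#'
#' @param n_subjects Cohort size (positive integer).
#' @param n_regions Number of geographic regions (>= 2; default 10).
#' @param period_boundary Calendar time (years) splitting period 1 entrants
#'   from period 2 entrants (default 10).
#' @param horizon Prediction horizon in years (default 10).
#' @param p_base Baseline mixture probability in (0, 1): the lifetime
#'   cause-1 probability of a subject with linear predictor 0.
#' @param event_time_rate Exponential rate shaping conditional cause-1
#'   times (per year); with the default 0.18, about 84% of eventual cause-1
#'   events occur within 10 years.
#' @param competing_rate Baseline hazard of the competing event (per year).
#' @param beta_sub Named coefficient vector for the cause-1 subdistribution
#'   linear predictor (terms produced by [cohort_design()]).
#' @param beta_competing Named coefficient vector for the competing-event
#'   log-hazard.
#' @param censor_rate Censoring hazard per year (>= 0).
#' @param period2_rate_multiplier Positive scalar (< 1 emulates falling
#'   mortality in period 2), multiplying both the cause-1 subdistribution
#'   exponent and the competing-event hazard for period-2 entrants.
#' @param region_sigma SD of Gaussian region-level intercepts added to both
#'   linear predictors.
#' @param p_period1 Probability that a subject enters in period 1.
#' @param mar_config Missing-at-random configuration: named list of
#'   coefficient triplets `c(intercept, b_age, b_period1)` on the logit
#'   scale, one per maskable covariate (conditioning only on fully observed
#'   age and period). See [default_mar_config()].
#' @param seed Integer seed for reproducibility.
#' @return A list of class `crp_sim_config`.
#' @export
sim_config <- function(n_subjects = 20000,
                       n_regions = 10,
                       period_boundary = 10,
                       horizon = 10,
                       p_base = 0.15,
                       event_time_rate = 0.18,
                       competing_rate = 0.008,
                       beta_sub = default_beta_sub(),
                       beta_competing = default_beta_competing(),
                       censor_rate = 0.03,
                       period2_rate_multiplier = 0.83,
                       region_sigma = 0.08,
                       p_period1 = 0.42,
                       mar_config = default_mar_config(),
                       seed = 1L) {
  if (n_subjects <= 0) stop("`n_subjects` must be positive", call. = FALSE)
  if (n_regions < 2) stop("`n_regions` must be >= 2", call. = FALSE)
  if (p_base <= 0 || p_base >= 1) stop("`p_base` must lie in (0, 1)", call. = FALSE)
  if (period2_rate_multiplier <= 0) stop("`period2_rate_multiplier` must be > 0", call. = FALSE)
  if (censor_rate < 0) stop("`censor_rate` must be >= 0", call. = FALSE)
  if (length(beta_sub) == 0 || length(beta_competing) == 0)
    stop("coefficient vectors must be non-empty", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    period_boundary = period_boundary, horizon = horizon, p_base = p_base,
    event_time_rate = event_time_rate, competing_rate = competing_rate,
    beta_sub = beta_sub, beta_competing = beta_competing,
    censor_rate = censor_rate,
    period2_rate_multiplier = period2_rate_multiplier,
    region_sigma = region_sigma, p_period1 = p_period1,
    mar_config = mar_config, seed = as.integer(seed)
  ), class = "crp_sim_config")
}

#' Default cause-1 subdistribution coefficients
#'
#' Generator ground truth on the design produced by [cohort_design()].
#' These values are artifact choices (the real covariate-outcome process is
#' unobservable); they encode a non-linear age effect, a protective receptor
#' profile, and strongly prognostic stage/grade, and yield a 10-year
#' cause-1 cumulative incidence of roughly 15-20%.
#' @return Named numeric vector.
#' @export
default_beta_sub <- function() {
  c(z_age = 0.35, z_age2 = 0.18, z_lbmi = 0.12, z_depriv = 0.06,
    stageII = 0.50, stageIII = 1.10, stageIV = 1.90,
    grade2 = 0.30, grade3 = 0.70,
    er_pos = -0.50, pr_pos = -0.30, her2_pos = 0.20,
    route_screen = -0.40, route_emergency = 0.60,
    smoke_ex = 0.05, smoke_light = 0.20, smoke_heavy = 0.45,
    hypertension = 0.10, diabetes2 = 0.15, hrt = -0.10, ssri = 0.10)
}

#' Default competing-event log-hazard coefficients
#' @return Named numeric vector.
#' @export
default_beta_competing <- function() {
  c(z_age = 1.00, z_age2 = 0.25, z_lbmi = 0.10, z_depriv = 0.10,
    stageII = 0.10, stageIII = 0.25, stageIV = 0.45,
    grade2 = 0.00, grade3 = 0.10,
    er_pos = 0.00, pr_pos = 0.00, her2_pos = 0.00,
    route_screen = -0.20, route_emergency = 0.40,
    smoke_ex = 0.15, smoke_light = 0.35, smoke_heavy = 0.70,
    hypertension = 0.25, diabetes2 = 0.40, hrt = 0.00, ssri = 0.15)
}

#' Default missing-at-random configuration
#'
#' One logit-scale coefficient triplet `c(intercept, b_age, b_period1)` per
#' maskable covariate; missingness may depend only on the fully observed
#' standardized age and the period-1 indicator (more missingness in period
#' 1, emulating historically poorer recording).
#' @return Named list of numeric triplets.
#' @export
default_mar_config <- function() {
  list(bmi = c(-1.9, 0.10, 0.90),
       deprivation = c(-2.9, 0.00, 0.20),
       smoking = c(-2.8, 0.00, 1.30),
       stage = c(-1.2, 0.10, 1.20),
       grade = c(-1.3, 0.00, 0.60),
       er = c(-1.0, 0.00, 1.80),
       pr = c(-0.9, 0.00, 1.80),
       her2 = c(-1.0, 0.00, 1.80))
}

#' Generator design matrix from raw covariates
#'
#' Maps raw cohort covariates to the standardized terms on which the
#' generator's coefficient vectors are defined.
#'
#' @param data Cohort tibble with raw covariate columns.
#' @return Numeric matrix with columns named as in [default_beta_sub()].
#' @export
cohort_design <- function(data) {
  z_age <- (data$age - 63) / 14
  cbind(
    z_age = z_age, z_age2 = z_age^2 - 1,
    z_lbmi = (log(data$bmi) - log(27)) / 0.2,
    z_depriv = data$deprivation / 3,
    stageII = as.numeric(data$stage == "II"),
    stageIII = as.numeric(data$stage == "III"),
    stageIV = as.numeric(data$stage == "IV"),
    grade2 = as.numeric(data$grade == "moderate"),
    grade3 = as.numeric(data$grade == "poor"),
    er_pos = data$er, pr_pos = data$pr, her2_pos = data$her2,
    route_screen = as.numeric(data$route == "screening"),
    route_emergency = as.numeric(data$route == "emergency"),
    smoke_ex = as.numeric(data$smoking == "ex"),
    smoke_light = as.numeric(data$smoking == "light"),
    smoke_heavy = as.numeric(data$smoking == "heavy"),
    hypertension = data$hypertension, diabetes2 = data$diabetes2,
    hrt = data$hrt, ssri = data$ssri
  )
}

#' Draw raw cohort covariates
#'
#' Samples the baseline covariate layout (marginals loosely emulating a
#' national breast-cancer cohort: age ~ 63 (SD 14), BMI ~ 27, stage mostly
#' I-II, predominantly ER positive). Covariates are drawn independently;
#' their joint association with outcome comes entirely through the
#' simulated event process.
#'
#' @param n Number of subjects.
#' @param config A [sim_config()] (reserved for future marginal options).
#' @return Tibble of raw covariates.
#' @export
draw_covariates <- function(n, config) {
  tibble::tibble(
    age = pmin(pmax(stats::rnorm(n, 63, 14), 20), 97),
    bmi = exp(stats::rnorm(n, log(27), 0.2)),
    deprivation = stats::rnorm(n, 0, 3),
    stage = factor(sample(c("I", "II", "III", "IV"), n, TRUE,
                          prob = c(0.45, 0.40, 0.09, 0.06)),
                   levels = c("I", "II", "III", "IV"), ordered = TRUE),
    grade = factor(sample(c("well", "moderate", "poor"), n, TRUE,
                          prob = c(0.17, 0.51, 0.32)),
                   levels = c("well", "moderate", "poor")),
    er = stats::rbinom(n, 1, 0.85),
    pr = stats::rbinom(n, 1, 0.68),
    her2 = stats::rbinom(n, 1, 0.15),
    route = factor(sample(c("screening", "two_week_wait", "gp_referral",
                            "other", "emergency"), n, TRUE,
                          prob = c(0.29, 0.50, 0.11, 0.06, 0.04)),
                   levels = c("screening", "two_week_wait", "gp_referral",
                              "other", "emergency")),
    smoking = factor(sample(c("never", "ex", "light", "heavy"), n, TRUE,
                            prob = c(0.60, 0.24, 0.12, 0.04)),
                     levels = c("never", "ex", "light", "heavy")),
    hypertension = stats::rbinom(n, 1, 0.31),
    diabetes2 = stats::rbinom(n, 1, 0.08),
    hrt = stats::rbinom(n, 1, 0.06),
    ssri = stats::rbinom(n, 1, 0.09)
  )
}

#' Simulate competing-risks event times from a covariate matrix
#'
#' Low-level generator realising the Fine-Gray mixture: cause-1 lifetime
#' probability P(cause 1 | X) = 1 - (1 - p_base)^exp(lp1), conditional
#' cause-1 times by inverse transform of the subdistribution, cause-2 times
#' exponential with log-hazard lp2, independent exponential censoring, and
#' administrative censoring at the horizon.
#'
#' @param X Numeric matrix whose columns match `names(config$beta_sub)`.
#' @param config A [sim_config()] object.
#' @param offset_sub,offset_comp Optional per-subject additions to the two
#'   linear predictors (region intercepts, log period multipliers).
#' @return Tibble with columns `time` (in (0, horizon]), `cause` (0/1/2) and
#'   `truth` (the analytic subdistribution CIF at the horizon).
#' @export
simulate_event_times <- function(X, config, offset_sub = 0, offset_comp = 0) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  p <- config$p_base
  if (p <= 0 || p >= 1) stop("`p_base` must lie in (0, 1)", call. = FALSE)
  lam1 <- config$event_time_rate
  n <- nrow(X)
  eta1 <- exp(drop(X %*% config$beta_sub[colnames(X)]) + offset_sub)
  eta2 <- exp(drop(X %*% config$beta_competing[colnames(X)]) + offset_comp)

  p1_inf <- 1 - (1 - p)^eta1
  v <- stats::runif(n)
  is1 <- v <= p1_inf

  t_event <- numeric(n)
  # inverse transform of F1(t) = 1 - (1 - p(1 - exp(-lam1 t)))^eta1 at V
  inner <- 1 - (1 - (1 - v[is1])^(1 / eta1[is1])) / p
  inner <- pmin(pmax(inner, 1e-300), 1)
  t_event[is1] <- -log(inner) / lam1
  t_event[!is1] <- stats::rexp(sum(!is1),
                               rate = config$competing_rate * eta2[!is1])

  cens <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate) else rep(Inf, n)
  tt <- pmin(t_event, cens, config$horizon)
  cause <- ifelse(tt == t_event & t_event <= pmin(cens, config$horizon),
                  ifelse(is1, 1L, 2L), 0L)
  tt <- pmax(tt, .Machine$double.eps)

  truth <- 1 - (1 - p * (1 - exp(-lam1 * config$horizon)))^eta1
  tibble::tibble(time = tt, cause = as.integer(cause), truth = truth)
}

#' Generate a synthetic multi-region, two-period cohort
#'
#' Draws covariates, region and period labels, simulates competing-risks
#' follow-up via [simulate_event_times()] with Gaussian region intercepts on
#' both linear predictors and a multiplicative period-2 baseline reduction,
#' then injects missing-at-random gaps via [inject_missingness()]. Original
#' (pre-masking) values are kept in `.orig_*` columns for imputation-quality
#' diagnostics only.
#'
#' @param config A [sim_config()] object.
#' @return Cohort tibble: `id`, `entry` (calendar years), `region`,
#'   `period`, `time`, `cause`, `truth`, raw covariates (with `NA`s where
#'   masked) and `.orig_*` shadow columns.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "crp_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  cov <- draw_covariates(n, config)
  region <- sample.int(config$n_regions, n, replace = TRUE)
  # ethnicity analogue: composition varies by region (not an outcome driver),
  # giving meta-regression a genuinely heterogeneity-linked cluster covariate
  w_nonwhite <- 0.10 + 0.45 * (region - 1) / max(config$n_regions - 1, 1)
  nonwhite <- stats::runif(n) < w_nonwhite
  eth <- rep("white", n)
  eth[nonwhite] <- sample(c("asian", "black", "other"), sum(nonwhite), TRUE,
                          prob = c(0.45, 0.35, 0.20))
  cov$ethnicity <- factor(eth, levels = c("white", "asian", "black", "other"))
  period <- ifelse(stats::runif(n) < config$p_period1, 1L, 2L)
  b <- config$period_boundary
  entry <- ifelse(period == 1L, stats::runif(n, 0, b), stats::runif(n, b, 2 * b))

  u_sub <- stats::rnorm(config$n_regions, 0, config$region_sigma)
  u_comp <- stats::rnorm(config$n_regions, 0, config$region_sigma)
  log_mult <- ifelse(period == 2L, log(config$period2_rate_multiplier), 0)

  X <- cohort_design(cov)
  ev <- simulate_event_times(X, config,
                             offset_sub = u_sub[region] + log_mult,
                             offset_comp = u_comp[region] + log_mult)

  cohort <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(n), entry = entry,
                   region = region, period = period),
    ev, cov)
  inject_missingness(cohort, config$mar_config, seed = config$seed + 1L)
}

#' Inject missing-at-random gaps into a cohort
#'
#' Masks values of the configured covariates with probabilities given by a
#' logistic model in fully observed conditioning variables (standardized age
#' and the period-1 indicator). Original values are retained in `.orig_*`
#' shadow columns so that imputation quality can be assessed against truth.
#'
#' @param cohort Cohort tibble (with `age` and `period` observed).
#' @param mar_config Named list of logit coefficient triplets
#'   `c(intercept, b_age, b_period1)`; see [default_mar_config()].
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected and `.orig_*` columns added.
#' @export
inject_missingness <- function(cohort, mar_config, seed = 1L) {
  maskable <- names(mar_config)
  if (any(c("age", "period") %in% maskable))
    stop("cannot condition missingness on a maskable variable", call. = FALSE)
  set.seed(seed)
  z_age <- (cohort$age - 63) / 14
  p1 <- as.numeric(cohort$period == 1L)
  for (v in maskable) {
    co <- mar_config[[v]]
    pr <- stats::plogis(co[1] + co[2] * z_age + co[3] * p1)
    mask <- stats::runif(nrow(cohort)) < pr
    cohort[[paste0(".orig_", v)]] <- cohort[[v]]
    cohort[[v]][mask] <- NA
  }
  cohort
}

#' Split a cohort into temporally distinct period subcohorts
#'
#' Period-1 entrants who survive past the period boundary have their
#' follow-up truncated there (status censored at boundary - entry), so that
#' no period-1 follow-up crosses into period 2; both subcohorts already
#' respect the administrative horizon. This emulates two wholly temporally
#' distinct datasets for temporal-transportability assessment.
#'
#' @param cohort Cohort tibble with `entry`, `time`, `cause`, `period`.
#' @param period_boundary Calendar boundary (years) between the periods.
#' @return Named list with tibbles `period1` and `period2`.
#' @export
truncate_followup <- function(cohort, period_boundary) {
  if (all(cohort$entry >= period_boundary) && any(cohort$period == 1L))
    stop("period boundary precedes all entries", call. = FALSE)
  p1 <- dplyr::filter(cohort, .data$period == 1L)
  p2 <- dplyr::filter(cohort, .data$period == 2L)
  over <- p1$entry + p1$time > period_boundary
  p1$cause[over] <- 0L
  p1$time[over] <- period_boundary - p1$entry[over]
  p1 <- dplyr::filter(p1, .data$time > 0)
  list(period1 = p1, period2 = p2)
}

#' Write / read a cohort as delimited text
#'
#' Cohorts are stored as tab-separated text with one header row; missing
#' values are empty strings. Shadow `.orig_*` columns are dropped on write.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   tibble with factor levels restored.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, !startsWith(names(cohort), ".orig_")]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, sep = "\t", na.strings = "",
                         stringsAsFactors = FALSE)
  x <- tibble::as_tibble(x)
  if ("stage" %in% names(x))
    x$stage <- factor(x$stage, levels = c("I", "II", "III", "IV"), ordered = TRUE)
  if ("grade" %in% names(x))
    x$grade <- factor(x$grade, levels = c("well", "moderate", "poor"))
  if ("route" %in% names(x))
    x$route <- factor(x$route, levels = c("screening", "two_week_wait",
                                          "gp_referral", "other", "emergency"))
  if ("smoking" %in% names(x))
    x$smoking <- factor(x$smoking, levels = c("never", "ex", "light", "heavy"))
  if ("ethnicity" %in% names(x))
    x$ethnicity <- factor(x$ethnicity, levels = c("white", "asian", "black",
                                                  "other"))
  x
}
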