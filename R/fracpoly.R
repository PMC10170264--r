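#' Fractional polynomial basis
#'
#' Builds the power-transform basis from the conventional power set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 means log). A repeated power (p, p)
#' yields the columns x^p and x^p * log(x). Values are shifted to be
#' positive and scaled before transformation; the shift/scale used are
#' returned as attributes so that new data can be transformed identically.
#'
#' @param x Numeric vector.
#' @param powers Numeric vector of 1 or 2 powers from the fixed set.
#' @param shift,scale Positivity shift and scale; computed from `x` when
#'   `NULL` (shift makes min(x) positive; scale is a power of 10 of the
#'   range, following common fractional-polynomial practice).
#' @return Numeric matrix with one column per basis term and attributes
#'   `powers`, `shift`, `scale`.
#' @export
fp_basis <- function(x, powers, shift = NULL, scale = NULL) {
  stopifnot(length(powers) %in% 1:2, all(powers %in% fp_power_set()))
  if (is.null(shift)) {
    shift <- if (min(x, na.rm = TRUE) > 0) 0 else
      -min(x, na.rm = TRUE) + 0.05 * diff(range(x, na.rm = TRUE))
  }
  if (is.null(scale)) {
    rng <- diff(range(x + shift, na.rm = TRUE))
    scale <- if (rng > 0) 10^(floor(log10(rng))) else 1
  }
  xs <- pmax((x + shift) / scale, 1e-8)  # new data may undershoot the
                                         # training shift; keep transforms finite
  tr <- function(p) if (p == 0) log(xs) else xs^p
  cols <- if (length(powers) == 2 && powers[1] == powers[2]) {
    cbind(tr(powers[1]), tr(powers[1]) * log(xs))
  } else {
    do.call(cbind, lapply(sort(powers), tr))
  }
  colnames(cols) <- paste0("fp", seq_len(ncol(cols)))
  structure(cols, powers = sort(powers), shift = shift, scale = scale)
}

#' @rdname fp_basis
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Select a fractional polynomial specification for one variable
#'
#' Searches first-degree (8 candidates) and second-degree (36 candidate
#' pairs, including repeated powers) fractional polynomials by deviance
#' within the supplied model family, then applies a closed test at
#' `alpha`: best FP2 against the null (4 df), against linear (3 df), and
#' against best FP1 (2 df). The returned specification is linear when the
#' closed test stops early.
#'
#' @param x Numeric vector (>= 20 distinct values after shift required).
#' @param fitter Function `f(basis_matrix)` returning a deviance (-2
#'   log-likelihood, or quasi-deviance scaled by dispersion) for the model
#'   including the basis columns; `f(NULL)` must return the null-model
#'   deviance. See [fp_fitter_cox()] and [fp_fitter_pseudo()].
#' @param alpha Closed-test significance level (default 0.05).
#' @return A list of class `crp_fp_spec`: `powers`, `shift`, `scale`,
#'   `selected` (`"fp2"`, `"fp1"` or `"linear"`), `dev_table`.
#' @export
select_fp <- function(x, fitter, alpha = 0.05) {
  if (length(unique(x[!is.na(x)])) < 20)
    stop("need >= 20 distinct values for fractional polynomial selection",
         call. = FALSE)
  ps <- fp_power_set()
  base1 <- fp_basis(x, 1)   # fixes shift/scale
  shift <- attr(base1, "shift"); scale <- attr(base1, "scale")

  dev_null <- fitter(NULL)
  dev1 <- vapply(ps, function(p) fitter(fp_basis(x, p, shift, scale)), 0)
  pairs <- expand.grid(p1 = ps, p2 = ps)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  dev2 <- mapply(function(p1, p2) fitter(fp_basis(x, c(p1, p2), shift, scale)),
                 pairs$p1, pairs$p2)

  best1 <- ps[which.min(dev1)]
  best2 <- unlist(pairs[which.min(dev2), ])
  d_lin <- dev1[ps == 1]
  d_fp1 <- min(dev1)
  d_fp2 <- min(dev2)

  sel <- "linear"
  if (stats::pchisq(dev_null - d_fp2, df = 4, lower.tail = FALSE) < alpha &&
      stats::pchisq(d_lin - d_fp2, df = 3, lower.tail = FALSE) < alpha) {
    sel <- if (stats::pchisq(d_fp1 - d_fp2, df = 2, lower.tail = FALSE) < alpha)
      "fp2" else "fp1"
  }
  powers <- switch(sel, linear = 1, fp1 = best1, fp2 = unname(best2))
  structure(list(powers = powers, shift = shift, scale = scale, selected = sel,
                 deviances = c(null = dev_null, linear = d_lin,
                               fp1 = d_fp1, fp2 = d_fp2)),
            class = "crp_fp_spec")
}

#' @export
print.crp_fp_spec <- function(x, ...) {
  cat("<crp_fp_spec>", x$selected, "powers (",
      paste(x$powers, collapse = ", "), ")\n")
  invisible(x)
}

#' Deviance fitters for fractional polynomial selection
#'
#' `fp_fitter_cox` evaluates candidates by Cox partial likelihood (cause 1
#' as the event, competing deaths censored); `fp_fitter_pseudo` by the
#' quasi-deviance of the complementary log-log pseudovalue GLM (scaled by
#' the null-model dispersion so that deviance differences are on an
#' approximate chi-squared scale).
#'
#' @param time,cause Follow-up and cause code vectors.
#' @param pseudo Pseudovalue vector (for the pseudo fitter).
#' @param adjust Optional adjustment matrix included in every candidate.
#' @return A function suitable as the `fitter` argument of [select_fp()].
#' @export
fp_fitter_cox <- function(time, cause, adjust = NULL) {
  y <- survival::Surv(time, cause == 1)
  function(basis) {
    X <- if (is.null(basis)) adjust else cbind(basis, adjust)
    if (is.null(X)) {
      fit <- survival::coxph(y ~ 1)
      return(-2 * fit$loglik[1])
    }
    fit <- survival::coxph(y ~ X, ties = "efron")
    -2 * fit$loglik[2]
  }
}

#' @rdname fp_fitter_cox
#' @export
fp_fitter_pseudo <- function(pseudo, adjust = NULL) {
  disp <- NULL
  function(basis) {
    X <- cbind(basis, adjust)
    fit <- fit_pseudo_glm(pseudo, X)
    if (is.null(disp)) disp <<- max(fit$deviance / fit$df.residual, 1e-12)
    fit$deviance / disp
  }
}
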