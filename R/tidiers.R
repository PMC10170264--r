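#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy method for fitted Cox models
#' @param x A `crp_cox` object.
#' @param ... Unused.
#' @return Tibble of pooled terms with estimates, robust SEs, p-values and
#'   hazard ratios.
#' @export
tidy.crp_cox <- function(x, ...) {
  tibble::as_tibble(x$coefficients)[c("term", "variable", "estimate", "se",
                                      "df", "p", "hr")]
}

#' @rdname tidy.crp_cox
#' @export
glance.crp_cox <- function(x, ...) {
  tibble::tibble(n_predictors = length(x$predictors),
                 n_terms = nrow(x$coefficients),
                 s0 = x$s0, horizon = x$horizon)
}

#' Tidy method for pseudovalue cloglog models
#' @param x A `crp_cloglog` object.
#' @param ... Unused.
#' @return Tibble of pooled terms (subdistribution scale); `hr` is the
#'   exponentiated coefficient (subdistribution hazard ratio).
#' @export
tidy.crp_cloglog <- function(x, ...) {
  tibble::as_tibble(x$coefficients)[c("term", "variable", "estimate", "se",
                                      "df", "p", "hr")]
}

#' @rdname tidy.crp_cloglog
#' @export
glance.crp_cloglog <- function(x, ...) {
  tibble::tibble(n_predictors = length(x$predictors),
                 n_terms = nrow(x$coefficients), horizon = x$horizon)
}

#' Tidy method for meta-regression results
#' @param x A `crp_metareg` object.
#' @param ... Unused.
#' @return Coefficient tibble.
#' @export
tidy.crp_metareg <- function(x, ...) x$coefficients

#' @rdname tidy.crp_metareg
#' @export
glance.crp_metareg <- function(x, ...) {
  tibble::tibble(r2 = x$r2, i2_residual = x$i2_residual, tau2 = x$tau2,
                 tau2_null = x$tau2_null, k = x$k)
}

#' Tidy method for IECV results
#' @param x A `crp_iecv` object.
#' @param ... Unused.
#' @return The HKSJ pooled summary table (one row per model x metric, with
#'   95% CI and 95% prediction interval).
#' @export
tidy.crp_iecv <- function(x, ...) x$meta

#' @rdname tidy.crp_iecv
#' @export
glance.crp_iecv <- function(x, ...) {
  tibble::tibble(models = paste(x$config$models, collapse = ","),
                 cycles = nrow(x$audit),
                 m = x$config$m,
                 leakage = sum(x$audit$overlap))
}
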