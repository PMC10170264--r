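#' Candidate predictors of the standard cohort layout
#'
#' @return Character vector of the covariates the pipeline treats as
#'   candidate predictors (continuous: age, bmi, deprivation; tumour
#'   factors: stage, grade, receptor binaries, route; smoking; comorbidity
#'   and drug flags).
#' @export
candidate_predictors <- function() {
  c("age", "bmi", "deprivation", "stage", "grade", "er", "pr", "her2",
    "route", "smoking", "hypertension", "diabetes2", "hrt", "ssri")
}

# Classify a predictor column for the selection rule.
predictor_type <- function(x) {
  if (is.factor(x)) return("categorical")
  if (is.numeric(x) && all(x %in% c(0, 1))) return("binary")
  "continuous"
}

#' Build a model design matrix from a cohort table
#'
#' Continuous predictors enter through their fractional-polynomial basis
#' when a spec is supplied (linear otherwise), factors are dummy-coded
#' (first level reference), binaries enter as 0/1. The returned matrix
#' carries a term-to-variable map (used by the predictor-selection rule)
#' and, when requested, centering constants (continuous terms centred at
#' the mean, binary/dummy terms at zero).
#'
#' @param data Cohort tibble.
#' @param predictors Character vector of predictor names.
#' @param fp_specs Named list of `crp_fp_spec` objects for continuous
#'   predictors (missing or `"linear"` specs give a single raw column).
#' @param use_fp Use fractional-polynomial bases (set `FALSE` for the
#'   machine-learning design, which uses untransformed continuous values).
#' @return Numeric matrix with attributes `var_map` (variable per column),
#'   `type_map` (predictor type per column) and `centers`.
#' @export
build_design <- function(data, predictors, fp_specs = list(), use_fp = TRUE) {
  cols <- list(); var_map <- character(); type_map <- character()
  for (v in predictors) {
    x <- data[[v]]
    if (is.null(x)) stop("missing predictor value column: ", v, call. = FALSE)
    ty <- predictor_type(x)
    if (ty == "continuous") {
      sp <- fp_specs[[v]]
      if (use_fp && !is.null(sp) && sp$selected != "linear") {
        b <- fp_basis(x, sp$powers, sp$shift, sp$scale)
        colnames(b) <- paste0(v, "_fp", seq_len(ncol(b)))
      } else {
        b <- matrix(x, ncol = 1, dimnames = list(NULL, v))
      }
    } else if (ty == "binary") {
      b <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, v))
    } else {
      mm <- stats::model.matrix(~ x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, sub("^x", "", colnames(mm)))
      b <- mm
    }
    cols[[v]] <- b
    var_map <- c(var_map, rep(v, ncol(b)))
    type_map <- c(type_map, rep(ty, ncol(b)))
  }
  X <- do.call(cbind, cols)
  centers <- ifelse(type_map == "continuous", colMeans(X), 0)
  names(centers) <- colnames(X)
  structure(X, var_map = stats::setNames(var_map, colnames(X)),
            type_map = stats::setNames(type_map, colnames(X)),
            centers = centers)
}

# Quasi-likelihood GLM of pseudovalues with a complementary log-log link.
# Pseudovalues may lie outside [0, 1]; a constant-variance quasi family
# accommodates them and sandwich errors account for their non-independence.
fit_pseudo_glm <- function(pseudo, X = NULL) {
  df <- if (is.null(X)) data.frame(y = pseudo)
        else data.frame(y = pseudo, X, check.names = FALSE)
  mustart <- pmin(pmax(pseudo, 0.001), 0.999)
  stats::glm(y ~ ., data = df,
             family = stats::quasi(link = "cloglog", variance = "constant"),
             mustart = mustart, control = stats::glm.control(maxit = 100))
}
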