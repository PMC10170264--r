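#' Machine-learning model specification for pseudovalue regression
#'
#' Declares the learner (gradient-boosted trees or feed-forward neural
#' network), its hyperparameter search ranges, and preprocessing. Both
#' learners use the jackknife pseudovalues of the 10-year cumulative
#' incidence as a continuous squared-error target; categorical predictors
#' are dummy coded, and the neural network additionally min-max scales all
#' inputs to \[0, 1\].
#'
#' Default ranges (gbt): boosting rounds 1-500, learning rate 1e-4-0.1,
#' tree depth 1-6, subsample 0.1-0.5, alpha/gamma/lambda 0-20, column
#' sampling by tree/level 0.1-0.8. Default ranges (ffnn): 1-5 hidden
#' layers, 26-50 nodes per layer, 1-50 epochs, initial learning rate
#' 0.001-0.1, batch size 1024.
#'
#' @param learner `"gbt"` or `"ffnn"`.
#' @param ranges Optional named list of `c(min, max)` ranges overriding the
#'   defaults (e.g. to cap hidden layers at desk scale).
#' @return A list of class `crp_ml_spec`.
#' @export
ml_spec <- function(learner = c("gbt", "ffnn"), ranges = NULL) {
  learner <- match.arg(learner)
  base <- if (learner == "gbt") {
    list(nrounds = c(1, 500), eta = c(1e-4, 0.1), max_depth = c(1, 6),
         subsample = c(0.1, 0.5), alpha = c(0, 20), gamma = c(0, 20),
         lambda = c(0, 20), colsample_bytree = c(0.1, 0.8),
         colsample_bylevel = c(0.1, 0.8))
  } else {
    list(n_layers = c(1, 5), n_nodes = c(26, 50), epochs = c(1, 50),
         lr = c(0.001, 0.1))
  }
  if (!is.null(ranges)) base[names(ranges)] <- ranges
  structure(list(learner = learner, ranges = base, tuned = NULL,
                 fitted = NULL, preproc = NULL),
            class = "crp_ml_spec")
}

ml_int_params <- c("nrounds", "max_depth", "n_layers", "n_nodes", "epochs")
ml_log_params <- c("eta", "lr")

# Default (untuned) configuration: mid-range values, log-mid for rates.
ml_default_config <- function(spec) {
  cfg <- lapply(names(spec$ranges), function(p) {
    r <- spec$ranges[[p]]
    v <- if (p %in% ml_log_params) sqrt(max(r[1], 1e-12) * r[2]) else mean(r)
    if (p %in% ml_int_params) round(v) else v
  })
  names(cfg) <- names(spec$ranges)
  cfg
}

# Deterministic candidate stream: config i is the i-th draw from the seeded
# uniform stream, so a larger budget evaluates a superset of candidates.
ml_draw_configs <- function(spec, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cfg <- lapply(names(spec$ranges), function(p) {
      r <- spec$ranges[[p]]
      v <- if (p %in% ml_log_params)
        exp(stats::runif(1, log(max(r[1], 1e-12)), log(r[2])))
      else stats::runif(1, r[1], r[2])
      if (p %in% ml_int_params) round(v) else v
    })
    names(cfg) <- names(spec$ranges)
    cfg
  })
}

check_config_in_ranges <- function(spec, cfg) {
  for (p in names(spec$ranges)) {
    r <- spec$ranges[[p]]
    if (cfg[[p]] < r[1] - 1e-9 || cfg[[p]] > r[2] + 1e-9)
      stop("tuned value for `", p, "` lies outside the declared range",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Preprocess a cohort table for the machine-learning learners
#'
#' Dummy codes multilevel categoricals (untransformed continuous values;
#' no fractional polynomials or interactions) and, for the neural network,
#' min-max scales every column to \[0, 1\] using constants stored for
#' reuse at prediction time.
#'
#' @param data Cohort tibble.
#' @param predictors Character vector of predictors.
#' @param preproc Preprocessing constants from a previous call (training);
#'   `NULL` derives them from `data`.
#' @param scale Min-max scale inputs (`TRUE` for the ffnn).
#' @return List with `X` (numeric matrix) and `preproc`.
#' @export
ml_preprocess <- function(data, predictors, preproc = NULL, scale = FALSE) {
  X <- build_design(data, predictors, fp_specs = list(), use_fp = FALSE)
  X <- X[, , drop = FALSE]
  if (is.null(preproc)) {
    rng <- apply(X, 2, range)
    preproc <- list(columns = colnames(X), min = rng[1, ],
                    max = rng[2, ], scale = scale)
  }
  if (!all(preproc$columns %in% colnames(X)))
    stop("newdata lacks dummy columns seen in training", call. = FALSE)
  X <- X[, preproc$columns, drop = FALSE]
  if (preproc$scale) {
    span <- pmax(preproc$max - preproc$min, 1e-12)
    X <- sweep(sweep(X, 2, preproc$min), 2, span, "/")
    X <- pmin(pmax(X, 0), 1)
  }
  list(X = X, preproc = preproc)
}

ml_train_one <- function(spec, cfg, X, y, seed) {
  if (spec$learner == "gbt") {
    set.seed(seed)
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eval_metric = "rmse",
                    tree_method = "hist", eta = cfg$eta,
                    max_depth = cfg$max_depth, subsample = cfg$subsample,
                    alpha = cfg$alpha, gamma = cfg$gamma, lambda = cfg$lambda,
                    colsample_bytree = cfg$colsample_bytree,
                    colsample_bylevel = cfg$colsample_bylevel,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = cfg$nrounds, verbose = 0)
  } else {
    mlp_fit(X, y, hidden = rep(cfg$n_nodes, cfg$n_layers), lr = cfg$lr,
            epochs = cfg$epochs, seed = seed)
  }
}

ml_predict_raw <- function(spec, model, X) {
  if (spec$learner == "gbt") stats::predict(model, xgboost::xgb.DMatrix(X))
  else mlp_forward(model, X)
}

#' Tune hyperparameters by cross-validated RMSE
#'
#' Random search (the pluggable desk-scale default for the model-based
#' optimisation the framework calls for) over the declared ranges: the
#' default configuration plus `budget` seeded draws are each scored by
#' k-fold cross-validated root-mean-squared error between observed
#' pseudovalues and predictions, and the best configuration is returned.
#' By construction the returned configuration's CV-RMSE never exceeds the
#' default configuration's, and a larger budget (same seed) never yields a
#' worse best score.
#'
#' @param spec A `crp_ml_spec`.
#' @param X Numeric design matrix (already preprocessed).
#' @param y Pseudovalue target.
#' @param k_folds Cross-validation folds (>= 2; default 5).
#' @param budget Number of random candidates (>= 1).
#' @param seed Integer seed (candidate stream and fold assignment).
#' @param max_rows Optional cap on rows used during tuning (random subset;
#'   the final fit always uses all rows).
#' @return The spec with `tuned` (best configuration) and attributes
#'   `cv_rmse` (best) and `cv_table` (all candidates).
#' @export
tune_hyperparameters <- function(spec, X, y, k_folds = 5, budget = 15,
                                 seed = 1L, max_rows = Inf) {
  stopifnot(inherits(spec, "crp_ml_spec"))
  if (k_folds < 2) stop("`k_folds` must be >= 2", call. = FALSE)
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  set.seed(seed)
  if (nrow(X) > max_rows) {
    keep <- sample.int(nrow(X), max_rows)
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  fold <- sample(rep_len(seq_len(k_folds), nrow(X)))
  cands <- c(list(ml_default_config(spec)),
             ml_draw_configs(spec, budget, seed + 1L))
  scores <- vapply(seq_along(cands), function(ci) {
    cfg <- cands[[ci]]
    sq <- 0
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      m <- ml_train_one(spec, cfg, X[tr, , drop = FALSE], y[tr],
                        seed = seed + 100L * ci + f)
      pr <- ml_predict_raw(spec, m, X[!tr, , drop = FALSE])
      sq <- sq + sum((pr - y[!tr])^2)
    }
    sqrt(sq / nrow(X))
  }, 0)
  best <- which.min(scores)
  spec$tuned <- cands[[best]]
  check_config_in_ranges(spec, spec$tuned)
  attr(spec, "cv_rmse") <- scores[best]
  attr(spec, "cv_default_rmse") <- scores[1]
  attr(spec, "cv_table") <- scores
  spec
}

#' Fit a pseudovalue-target machine-learning model
#'
#' Trains the learner on the (stacked) design with the squared-error
#' objective on pseudovalues, using the tuned configuration when present
#' and the default configuration otherwise.
#'
#' @param spec A `crp_ml_spec` (tuned or not).
#' @param X Numeric design matrix from [ml_preprocess()].
#' @param y Pseudovalue target.
#' @param seed Integer seed.
#' @return The spec with `fitted` model attached.
#' @export
fit_pseudo_ml <- function(spec, X, y, seed = 1L) {
  if (any(!is.finite(y))) stop("non-finite pseudovalue target", call. = FALSE)
  cfg <- spec$tuned %||% ml_default_config(spec)
  check_config_in_ranges(spec, cfg)
  spec$fitted <- ml_train_one(spec, cfg, X, y, seed)
  spec$config <- cfg
  spec
}

#' Predicted event probability from a fitted ML model
#'
#' Raw predictions target pseudovalues and may fall outside \[0, 1\]; they
#' are clipped to \[0, 1\] to represent probabilities.
#'
#' @param object A fitted `crp_ml_spec`.
#' @param newdata Preprocessed numeric matrix (use the training `preproc`).
#' @param type `"risk"` (clipped, default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.crp_ml_spec <- function(object, newdata, type = c("risk", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(object$fitted)) stop("model has not been fitted", call. = FALSE)
  raw <- ml_predict_raw(object, object$fitted, newdata)
  if (type == "raw") raw else pmin(pmax(raw, 0), 1)
}

#' @export
print.crp_ml_spec <- function(x, ...) {
  cat("<crp_ml_spec>", x$learner,
      if (!is.null(x$fitted)) "(fitted)" else if (!is.null(x$tuned))
        "(tuned)" else "(unfitted)", "\n")
  invisible(x)
}
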