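#' Serialise regression models to a documented text format
#'
#' Writes a `crp_cox` or `crp_cloglog` model as JSON (full numeric
#' precision) containing the coefficient table, centering constants,
#' baseline survival, fractional-polynomial specifications and predictor
#' list, so that reloaded models reproduce predictions bit for bit.
#'
#' @param model A `crp_cox` or `crp_cloglog` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("crp_cox", "crp_cloglog")))
  # doubles travel as %.17g strings: decimal JSON numbers do not round-trip
  # exactly, 17 significant digits do
  num <- function(x) sprintf("%.17g", x)
  fp <- lapply(model$fp_specs, function(s)
    list(powers = num(s$powers), shift = num(s$shift), scale = num(s$scale),
         selected = s$selected))
  co <- model$coefficients
  payload <- list(
    class = class(model)[1],
    horizon = num(model$horizon),
    predictors = model$predictors,
    coefficients = list(term = co$term, estimate = num(co$estimate),
                        se = num(co$se), df = num(co$df)),
    fp_specs = fp)
  if (inherits(model, "crp_cox")) {
    payload$s0 <- num(model$s0)
    payload$centers <- as.list(stats::setNames(num(model$centers),
                                               names(model$centers)))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- lapply(p$fp_specs, function(s)
    structure(list(powers = as.numeric(s$powers), shift = as.numeric(s$shift),
                   scale = as.numeric(s$scale), selected = s$selected),
              class = "crp_fp_spec"))
  co <- tibble::tibble(term = p$coefficients$term,
                       estimate = as.numeric(p$coefficients$estimate),
                       se = as.numeric(p$coefficients$se),
                       df = as.numeric(p$coefficients$df))
  obj <- list(coefficients = co, predictors = p$predictors,
              fp_specs = fp, horizon = as.numeric(p$horizon))
  if (p$class == "crp_cox") {
    obj$s0 <- as.numeric(p$s0)
    obj$centers <- vapply(p$centers, as.numeric, 0)
  }
  structure(obj, class = p$class)
}

#' Write the IECV result tables and figures
#'
#' Renders the analysis outputs as delimited text (region-level metrics,
#' HKSJ pooled summary with confidence and prediction intervals, forest
#' plot input tables, the leakage audit) and standard PDF figures
#' (calibration and decision curves) plus a run-metadata file.
#'
#' @param result A `crp_iecv` object.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of files written.
#' @export
make_report <- function(result, dir) {
  stopifnot(inherits(result, "crp_iecv"))
  if (nrow(result$meta) == 0) stop("empty result: nothing to report", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(x, name) {
    f <- file.path(dir, name)
    utils::write.table(x, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wr(result$cluster_metrics, "cluster_metrics.tsv")
  wr(result$meta, "meta_summary.tsv")
  forest <- result$cluster_metrics |>
    dplyr::mutate(ci_low = .data$value - 1.96 * .data$se,
                  ci_high = .data$value + 1.96 * .data$se, row = "region") |>
    dplyr::bind_rows(result$meta |>
                       dplyr::mutate(value = .data$estimate, row = "pooled"))
  wr(forest, "forest_input.tsv")
  wr(result$audit, "leakage_audit.tsv")

  risk_cols <- grep("^risk_", names(result$predictions), value = TRUE)
  if (length(risk_cols) > 0) {
    grDevices::pdf(file.path(dir, "calibration.pdf"), width = 8, height = 5)
    for (rc in risk_cols) {
      model <- sub("^risk_", "", rc)
      ps <- if (model == "cox") result$predictions$pseudo_km
            else result$predictions$pseudo_cif
      cc <- smoothed_calibration_curve(result$predictions[[rc]], ps)
      print(ggplot2::autoplot(cc) + ggplot2::ggtitle(model))
    }
    grDevices::dev.off()
    files <- c(files, file.path(dir, "calibration.pdf"))

    grDevices::pdf(file.path(dir, "decision_curves.pdf"), width = 8, height = 5)
    for (rc in risk_cols) {
      dc <- decision_curve(result$predictions$time, result$predictions$cause,
                           result$predictions[[rc]],
                           horizon = result$config$horizon,
                           thresholds = result$config$thresholds)
      print(ggplot2::autoplot(dc) + ggplot2::ggtitle(sub("^risk_", "", rc)))
    }
    grDevices::dev.off()
    files <- c(files, file.path(dir, "decision_curves.pdf"))
  }
  meta_f <- file.path(dir, "run_metadata.txt")
  writeLines(c(paste("models:", paste(result$config$models, collapse = ",")),
               paste("seed:", result$config$seed),
               paste("m:", result$config$m),
               paste("cycles:", nrow(result$audit))), meta_f)
  files <- c(files, meta_f)
  invisible(files)
}
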