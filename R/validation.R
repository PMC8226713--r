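#' Goodness of fit between observed and predicted values
#'
#' r2 = 1 - SSE/SST with SST about the observed mean;
#' adjusted r2 = 1 - (1 - r2)(n - 1)/(n - p - 1); rmse = sqrt(SSE / n)
#' (denominator n, not n - p; recorded in the report so values are
#' interpretable).
#'
#' @param observed,predicted equal-length numeric vectors (percent).
#' @param p number of model parameters, used for the adjustment
#'   (default `NA`: adjusted r2 not computed).
#' @return an object of class `fit_report` with fields `r2`, `adjusted_r2`,
#'   `rmse`, `n`, `p` and the observed/predicted `pairs` kept for plotting.
#' @export
goodness_of_fit <- function(observed, predicted, p = NA) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("observed values have zero variance; r2 is undefined",
         call. = FALSE)
  }
  sse <- sum((observed - predicted)^2)
  r2 <- 1 - sse / sst
  adjusted_r2 <- if (!is.na(p) && n > p + 1) {
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else NA_real_
  structure(list(r2 = r2, adjusted_r2 = adjusted_r2,
                 rmse = sqrt(sse / n), rmse_denominator = "n",
                 n = n, p = p,
                 pairs = data.frame(observed = observed,
                                    predicted = predicted)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> n = %d: r2 = %.4f, adjusted r2 = %s, rmse = %.4g\n",
              x$n, x$r2,
              if (is.na(x$adjusted_r2)) "NA" else sprintf("%.4f", x$adjusted_r2),
              x$rmse))
  invisible(x)
}

#' External validation on a held-out storage temperature
#'
#' Predicts every hold-out observation with the supplied model and returns
#' a [goodness_of_fit] report. If the model records the temperatures it was
#' fitted on, any overlap with the hold-out temperatures is refused as
#' leakage.
#'
#' @param predictor a [kinetic_model] or `mlp_ensemble`.
#' @param holdout an [sh_dataset] at the reserved temperature(s), percent
#'   units.
#' @param ... passed to methods.
#' @return a `fit_report`.
#' @export
external_validate <- function(predictor, holdout, ...) {
  UseMethod("external_validate")
}

check_leakage <- function(trained_temps_c, holdout) {
  if (is.null(trained_temps_c)) return(invisible(NULL))
  leaked <- intersect(unique(holdout$temperature_c), trained_temps_c)
  if (length(leaked) > 0) {
    stop("leakage: hold-out temperature(s) ",
         paste(leaked, collapse = ", "),
         " degC were used to build the predictor", call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname external_validate
#' @export
external_validate.kinetic_model <- function(predictor, holdout, ...) {
  stopifnot(inherits(holdout, "sh_dataset"))
  check_leakage(predictor$fitted_temperatures_c, holdout)
  sub <- holdout[holdout$treatment == predictor$treatment &
                   holdout$heat_state == predictor$heat_state, ,
                 drop = FALSE]
  if (nrow(sub) == 0) {
    stop("hold-out data contain no observations for group ",
         predictor$treatment, "/", predictor$heat_state, call. = FALSE)
  }
  pred <- predict_sh(predictor, sub$time_days,
                     temperature_c = sub$temperature_c)
  goodness_of_fit(sub$sh_value, pred, p = 2)
}

#' @rdname external_validate
#' @export
external_validate.mlp_ensemble <- function(predictor, holdout, ...) {
  stopifnot(inherits(holdout, "sh_dataset"))
  check_leakage(predictor$trained_temperatures_c, holdout)
  pred <- ensemble_predict(predictor, holdout)
  goodness_of_fit(holdout$sh_value, pred, p = predictor$n_weights)
}

#' Predicted-vs-observed scatter plot
#'
#' Writes the classic validation figure: predicted against observed values
#' with the identity line (perfect match) and the report's r2/rmse
#' annotated.
#'
#' @param report a `fit_report` with non-empty `pairs`.
#' @param path output image path (format from extension, e.g. `.png`,
#'   `.pdf`).
#' @param title optional plot title.
#' @return `path`, invisibly.
#' @export
scatter_report <- function(report, path, title = "Predicted vs observed SH") {
  stopifnot(inherits(report, "fit_report"))
  pairs <- report$pairs
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("report carries no observed/predicted pairs to plot", call. = FALSE)
  }
  label <- sprintf("r2 = %.3f\nrmse = %.2f", report$r2, report$rmse)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = observed, y = predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "solid",
                         colour = "grey30") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.2,
                      label = label) +
    ggplot2::labs(x = "Observed SH (%)", y = "Predicted SH (%)",
                  title = title) +
    ggplot2::theme_minimal()
  ok <- tryCatch({
    ggplot2::ggsave(path, p, width = 5, height = 5, dpi = 150)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write plot to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
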