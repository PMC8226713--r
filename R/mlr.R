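#' Dummy-coded design matrix for treatment-effect regression
#'
#' Columns: intercept, one indicator per non-reference treatment (the
#' reference — control by default — carries no dummy), storage temperature
#' in degC and time in days, both untransformed so the slopes read directly
#' in percent per degC and percent per day. Raw and cooked meat are fitted
#' separately, so the dataset is restricted to one heat state.
#'
#' @param dataset an [sh_dataset] in percent units.
#' @param heat_state which heat state to model (`"raw"` or `"cooked"`).
#' @param reference reference treatment level (default `"control"`).
#' @return list with `x` (design matrix), `y` (SH %), `reference`,
#'   `heat_state` and `treatments` (non-reference levels, design order).
#' @export
build_design_matrix <- function(dataset, heat_state = "raw",
                                reference = "control") {
  stopifnot(inherits(dataset, "sh_dataset"))
  if (dataset_unit(dataset) != "percent") {
    stop("dataset must be in percent units", call. = FALSE)
  }
  heat_state <- match.arg(heat_state, HEAT_STATES)
  df <- as.data.frame(dataset)[dataset$heat_state == heat_state, ,
                               drop = FALSE]
  if (nrow(df) == 0) {
    stop("no observations for heat_state = ", heat_state, call. = FALSE)
  }
  present <- unique(df$treatment)
  if (!reference %in% present) {
    stop("reference level `", reference, "` absent from the data",
         call. = FALSE)
  }
  missing_treatments <- setdiff(TREATMENT_LEVELS, present)
  if (length(missing_treatments) > 0 &&
      all(present %in% TREATMENT_LEVELS)) {
    warning("treatment level(s) absent from the data: ",
            paste(missing_treatments, collapse = ", "),
            "; fitting ", length(setdiff(present, reference)),
            " dummies", call. = FALSE)
  }
  others <- setdiff(intersect(TREATMENT_LEVELS, present), reference)
  if (length(others) == 0) others <- setdiff(sort(present), reference)
  dummies <- vapply(others, function(lv) as.numeric(df$treatment == lv),
                    numeric(nrow(df)))
  dummies <- matrix(dummies, nrow = nrow(df),
                    dimnames = list(NULL, paste0("treatment_", others)))
  x <- cbind(`(Intercept)` = 1, dummies,
             temperature_c = df$temperature_c,
             time_days = df$time_days)
  if (qr(x)$rank < ncol(x)) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  list(x = x, y = df$sh_value, reference = reference,
       heat_state = heat_state, treatments = others)
}

#' Fit the dummy-coded multiple regression
#'
#' Ordinary least squares of SH on the design of [build_design_matrix],
#' with classical (homoscedastic) standard errors, two-sided t-tests of
#' each coefficient against zero, and the overall model F-test.
#'
#' @param design list from [build_design_matrix].
#' @param response optional response vector overriding `design$y`.
#' @return an object of class `mlr_fit` with per-term `coefficients`,
#'   `standard_errors`, `t_statistics`, `p_values`, plus `r2`, `see`
#'   (standard error of estimate), `f_pvalue` and `n`.
#' @export
fit_mlr <- function(design, response = NULL) {
  x <- design$x
  y <- if (is.null(response)) design$y else response
  stopifnot(length(y) == nrow(x))
  if (length(y) <= ncol(x)) {
    stop("need more observations than design columns", call. = FALSE)
  }
  fit <- lm(y ~ x - 1)
  sm <- summary(fit)
  ct <- sm$coefficients
  rownames(ct) <- sub("^x", "", rownames(ct))
  fstat <- sm$fstatistic
  structure(list(
    coefficients = ct[, "Estimate"],
    standard_errors = ct[, "Std. Error"],
    t_statistics = ct[, "t value"],
    p_values = ct[, "Pr(>|t|)"],
    r2 = {
      # intercept-only baseline (lm on a matrix without intercept term
      # reports uncentered r2, which is not what treatment comparisons use)
      sse <- sum(residuals(fit)^2)
      sst <- sum((y - mean(y))^2)
      1 - sse / sst
    },
    see = sm$sigma,
    f_pvalue = {
      sse <- sum(residuals(fit)^2)
      sst <- sum((y - mean(y))^2)
      df1 <- ncol(x) - 1
      df2 <- length(y) - ncol(x)
      f <- ((sst - sse) / df1) / (sse / df2)
      pf(f, df1, df2, lower.tail = FALSE)
    },
    n = length(y),
    reference = design$reference,
    heat_state = design$heat_state,
    treatments = design$treatments,
    lm_fit = fit
  ), class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf("<mlr_fit> %s meat, n = %d: r2 = %.3f, see = %.3f, F-test p = %.3g\n",
              x$heat_state, x$n, x$r2, x$see, x$f_pvalue))
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    t = x$t_statistics, p = x$p_values)
  print(round(tab, 4), ...)
  invisible(x)
}

#' Treatment-vs-control significance table
#'
#' One row per treatment dummy: the slope relative to control, its t-test
#' p-value and a significance flag at `p <= alpha` (boundary inclusive).
#' A positive slope means SH is preserved relative to control (antioxidant
#' effect); a negative slope means faster thiol loss (prooxidant).
#'
#' @param fit an `mlr_fit`.
#' @param alpha significance level (default 0.05).
#' @return data frame with columns `treatment`, `estimate`, `se`, `t`, `p`,
#'   `significant`, `effect`.
#' @export
compare_to_control <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mlr_fit"))
  terms <- grep("^treatment_", names(fit$coefficients), value = TRUE)
  if (length(terms) == 0) {
    stop("fit contains no treatment dummies", call. = FALSE)
  }
  data.frame(
    treatment = sub("^treatment_", "", terms),
    estimate = unname(fit$coefficients[terms]),
    se = unname(fit$standard_errors[terms]),
    t = unname(fit$t_statistics[terms]),
    p = unname(fit$p_values[terms]),
    significant = unname(fit$p_values[terms] <= alpha),
    effect = ifelse(fit$coefficients[terms] > 0, "antioxidant",
                    "prooxidant"),
    stringsAsFactors = FALSE, row.names = NULL)
}
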