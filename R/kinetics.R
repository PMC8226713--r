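#' Fit the zero-order decay rate at one temperature
#'
#' Ordinary least squares of SH (%) on time (days) for one
#' (treatment, heat_state, temperature) series; the decay rate constant is
#' k = -slope, reported positive for decaying series. With
#' `fix_intercept = TRUE` the intercept is pinned at SH0 = 100 and only the
#' slope is estimated.
#'
#' @param series an [sh_dataset] (or plain data frame with `time_days` and
#'   `sh_value`) at a single (treatment, heat_state, temperature).
#' @param fix_intercept pin the intercept at 100 (default `FALSE`).
#' @param average_replicates collapse replicates to their per-time mean
#'   before fitting (default `FALSE`: replicates enter as individual
#'   points).
#' @return an object of class `isothermal_fit` with fields `temperature_k`,
#'   `k`, `intercept`, `order`, `r2`, `rmse`, `n_points`.
#' @export
fit_zero_order <- function(series, fix_intercept = FALSE,
                           average_replicates = FALSE) {
  series <- as.data.frame(series)
  stopifnot(all(c("time_days", "sh_value") %in% names(series)))
  for (col in c("treatment", "heat_state", "temperature_c")) {
    if (col %in% names(series) && length(unique(series[[col]])) > 1) {
      stop("`series` mixes several values of `", col,
           "`; fit one group at a time", call. = FALSE)
    }
  }
  if (average_replicates) {
    agg <- tapply(series$sh_value, series$time_days, mean)
    series <- data.frame(time_days = as.numeric(names(agg)),
                         sh_value = as.numeric(agg))
  }
  t <- series$time_days
  y <- series$sh_value
  if (length(unique(t)) < 2) {
    stop("degenerate design: need >= 2 distinct time points", call. = FALSE)
  }
  if (fix_intercept) {
    # slope-only least squares through (0, 100)
    slope <- sum(t * (y - 100)) / sum(t^2)
    intercept <- 100
  } else {
    fit <- lm(y ~ t)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  }
  fitted_y <- intercept + slope * t
  sse <- sum((y - fitted_y)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(
    temperature_k = if ("temperature_c" %in% names(series))
      celsius_to_kelvin(series$temperature_c[1]) else NA_real_,
    temperature_c = if ("temperature_c" %in% names(series))
      series$temperature_c[1] else NA_real_,
    k = -slope,
    intercept = intercept,
    order = 0L,
    r2 = r2,
    rmse = sqrt(sse / length(y)),
    n_points = length(y),
    fix_intercept = fix_intercept
  ), class = "isothermal_fit")
}

#' @export
print.isothermal_fit <- function(x, ...) {
  cat(sprintf(
    "<isothermal_fit> T = %.2f K: k = %.5g %%/day, intercept = %.4g, r2 = %.4f, rmse = %.3g (n = %d)\n",
    x$temperature_k, x$k, x$intercept, x$r2, x$rmse, x$n_points))
  invisible(x)
}

#' Select the reaction order at one temperature
#'
#' Fits linear regressions of SH (order 0), ln SH (order 1) and 1/SH
#' (order 2) on time and returns the order whose regression has the highest
#' r-squared; ties (within `tol`) go to the lowest order.
#'
#' @param series observations at one temperature; all SH values must be
#'   strictly positive (required by the log and reciprocal transforms).
#' @param tol tie tolerance on r-squared (default 1e-9).
#' @return integer order, 0, 1 or 2.
#' @export
select_order <- function(series, tol = 1e-9) {
  series <- as.data.frame(series)
  t <- series$time_days
  y <- series$sh_value
  if (any(y <= 0)) {
    stop("non-positive SH value(s) at row(s) ",
         paste(head(which(y <= 0), 5), collapse = ", "),
         "; order selection needs SH > 0", call. = FALSE)
  }
  if (length(unique(t)) < 2) {
    stop("degenerate design: need >= 2 distinct time points", call. = FALSE)
  }
  r2_of <- function(resp) {
    fit <- lm(resp ~ t)
    sst <- sum((resp - mean(resp))^2)
    if (sst == 0) return(1)
    1 - sum(residuals(fit)^2) / sst
  }
  r2 <- c(r2_of(y), r2_of(log(y)), r2_of(1 / y))
  orders <- c(0L, 1L, 2L)
  orders[which(r2 >= max(r2) - tol)[1]]
}

#' Fit zero-order rate constants at every available temperature
#'
#' One [fit_zero_order] per storage temperature for a single
#' (treatment, heat_state) group, excluding the external-validation
#' hold-out temperature (default 12 degC; pass `holdout_temp_c = NULL` to
#' fit every temperature).
#'
#' @param dataset an [sh_dataset] in percent units.
#' @param treatment,heat_state group selector.
#' @param holdout_temp_c temperature(s) in degC to exclude, or `NULL`.
#' @param ... passed to [fit_zero_order].
#' @return list of `isothermal_fit`, ordered by temperature.
#' @export
fit_all_temperatures <- function(dataset, treatment, heat_state,
                                 holdout_temp_c = 12, ...) {
  stopifnot(inherits(dataset, "sh_dataset"))
  if (dataset_unit(dataset) != "percent") {
    stop("dataset must be normalized to percent units first", call. = FALSE)
  }
  grp <- dataset_group(dataset, treatment, heat_state)
  temps <- sort(unique(grp$temperature_c))
  if (!is.null(holdout_temp_c)) temps <- setdiff(temps, holdout_temp_c)
  if (length(temps) < 2) {
    stop("group ", treatment, "/", heat_state,
         " has < 2 usable temperatures", call. = FALSE)
  }
  fits <- lapply(temps, function(tc) {
    fit_zero_order(as.data.frame(grp)[grp$temperature_c == tc, ], ...)
  })
  names(fits) <- as.character(temps)
  fits
}

#' Tabulate a list of isothermal fits
#'
#' @param fits list of `isothermal_fit` (e.g. from [fit_all_temperatures]).
#' @return data frame with one row per temperature.
#' @export
isothermal_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(temperature_c = f$temperature_c,
               temperature_k = f$temperature_k,
               k = f$k, intercept = f$intercept, r2 = f$r2,
               rmse = f$rmse, n_points = f$n_points)
  }))
}
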