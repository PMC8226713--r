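#' Arrhenius parameter container
#'
#' @param k0 pre-exponential factor, day^-1; > 0.
#' @param ea activation energy, kJ/mol; finite.
#' @param r2 determination coefficient of the fit that produced the
#'   parameters (`NA` allowed for hand-built models).
#' @param method `"two_stage"` or `"global_lm"`.
#' @return an object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(k0, ea, r2 = NA_real_,
                             method = c("two_stage", "global_lm")) {
  method <- match.arg(method)
  stopifnot(is.numeric(k0), length(k0) == 1, k0 > 0,
            is.numeric(ea), length(ea) == 1, is.finite(ea))
  structure(list(k0 = k0, ea = ea, r2 = r2, method = method),
            class = "arrhenius_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf("<arrhenius_params> k0 = %.5g /day, Ea = %.4f kJ/mol (%s, r2 = %s)\n",
              x$k0, x$ea, x$method,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' Arrhenius rate constant at a temperature
#'
#' k(T) = k0 exp(-Ea / (R T)). As T grows without bound the rate approaches
#' k0, the rate at which the activation barrier no longer limits the
#' reaction.
#'
#' @param params an [arrhenius_params].
#' @param temperature_k absolute temperature(s), kelvin > 0.
#' @return rate constant(s), percent per day.
#' @export
rate_at <- function(params, temperature_k) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (any(temperature_k <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  params$k0 * exp(-params$ea / (R_GAS * temperature_k))
}

#' Two-stage Arrhenius fit from per-temperature rate constants
#'
#' Linear regression of ln k on 1/T: the slope is -Ea/R and the intercept
#' is ln k0. This is the classical linearization of the Arrhenius law.
#'
#' @param fits list of `isothermal_fit` (>= 2 distinct temperatures, all
#'   with k > 0).
#' @return an [arrhenius_params] with `method = "two_stage"`; `r2` is the
#'   determination coefficient of the ln k vs 1/T regression.
#' @export
fit_arrhenius_two_stage <- function(fits) {
  k <- vapply(fits, function(f) f$k, numeric(1))
  temp_k <- vapply(fits, function(f) f$temperature_k, numeric(1))
  if (any(k <= 0)) {
    stop("non-positive rate constant(s) at T = ",
         paste(temp_k[k <= 0], collapse = ", "),
         " K; cannot take logs", call. = FALSE)
  }
  if (length(unique(temp_k)) < 2) {
    stop("degenerate design: need rate constants at >= 2 distinct temperatures",
         call. = FALSE)
  }
  inv_t <- 1 / temp_k
  lnk <- log(k)
  if (max(lnk) - min(lnk) == 0) {
    # flat Arrhenius line: zero activation energy
    return(arrhenius_params(k0 = k[1], ea = 0, r2 = 1,
                            method = "two_stage"))
  }
  fit <- lm(lnk ~ inv_t)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  sst <- sum((lnk - mean(lnk))^2)
  r2 <- 1 - sum(residuals(fit)^2) / sst
  arrhenius_params(k0 = exp(intercept), ea = -slope * R_GAS, r2 = r2,
                   method = "two_stage")
}

#' Global Arrhenius fit by Levenberg-Marquardt
#'
#' Fits SH = 100 - k0 exp(-Ea / (R T)) t to all observations of one group
#' across temperatures at once, minimizing the residual sum of squares with
#' the Levenberg-Marquardt algorithm. The optimization runs over
#' (ln k0, Ea): k0 spans many orders of magnitude across treatments and the
#' log parameterization keeps it positive without bounds.
#'
#' @param series an [sh_dataset] (or data frame with `temperature_c`,
#'   `time_days`, `sh_value`) for one group, spanning >= 2 temperatures.
#' @param init optional [arrhenius_params] used as the starting point;
#'   default is the two-stage estimate from per-temperature fits, with a
#'   fallback of Ea = 60 kJ/mol and k0 matched to the mean observed rate.
#' @param sh0 fixed initial level (default 100).
#' @param maxiter iteration cap (default 500).
#' @param ftol relative SSE convergence tolerance (default 1e-10).
#' @return an [arrhenius_params] with `method = "global_lm"`; `r2` is the
#'   observed-vs-fitted determination coefficient.
#' @export
fit_arrhenius_global <- function(series, init = NULL, sh0 = 100,
                                 maxiter = 500, ftol = 1e-10) {
  df <- as.data.frame(series)
  stopifnot(all(c("temperature_c", "time_days", "sh_value") %in% names(df)))
  temps <- unique(df$temperature_c)
  if (length(temps) < 2) {
    stop("k0 and Ea are not identifiable from a single temperature",
         call. = FALSE)
  }
  temp_k <- celsius_to_kelvin(df$temperature_c)
  if (is.null(init)) {
    init <- tryCatch({
      fits <- lapply(sort(temps), function(tc) {
        fit_zero_order(df[df$temperature_c == tc, , drop = FALSE])
      })
      fit_arrhenius_two_stage(fits)
    }, error = function(e) NULL)
  }
  if (is.null(init)) {
    # fallback: mid-range activation energy, k0 matched to the mean
    # observed decay rate at the mean temperature
    ea0 <- 60
    nonzero <- df$time_days > 0
    mean_rate <- mean((sh0 - df$sh_value[nonzero]) / df$time_days[nonzero])
    mean_rate <- max(mean_rate, 1e-6)
    par0 <- c(lnk0 = log(mean_rate) + ea0 / (R_GAS * mean(temp_k)), ea = ea0)
  } else {
    par0 <- c(lnk0 = log(init$k0), ea = init$ea)
  }
  resid_fn <- function(par) {
    df$sh_value - (sh0 - exp(par[1] - par[2] / (R_GAS * temp_k)) * df$time_days)
  }
  out <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol))
  if (!out$info %in% 1:4) {
    cond <- structure(
      class = c("thiolkin_fit_failure", "error", "condition"),
      list(message = paste0(
             "Levenberg-Marquardt did not converge (info = ", out$info,
             ", ", out$message, "); last iterate lnk0 = ",
             signif(out$par[1], 6), ", ea = ", signif(out$par[2], 6),
             ", residual norm = ", signif(sqrt(out$deviance), 6)),
           call = sys.call(-1), par = out$par, deviance = out$deviance))
    stop(cond)
  }
  fitted_sh <- sh0 - exp(out$par[1] - out$par[2] / (R_GAS * temp_k)) *
    df$time_days
  sst <- sum((df$sh_value - mean(df$sh_value))^2)
  r2 <- if (sst > 0) 1 - sum((df$sh_value - fitted_sh)^2) / sst else NA_real_
  arrhenius_params(k0 = exp(unname(out$par[1])), ea = unname(out$par[2]),
                   r2 = r2, method = "global_lm")
}

#' Kinetic prediction model for one group
#'
#' Combines fixed SH0 (default 100%) with Arrhenius parameters into a
#' predictor SH(t, T) for one (treatment, heat_state) cell. The set of
#' temperatures used to fit the parameters can be recorded so external
#' validation can detect leakage of the hold-out temperature.
#'
#' @param treatment,heat_state group labels.
#' @param params an [arrhenius_params].
#' @param sh0 initial level, percent (default 100).
#' @param fitted_temperatures_c temperatures (degC) used in fitting, or
#'   `NULL` if unknown.
#' @return an object of class `kinetic_model`.
#' @export
kinetic_model <- function(treatment, heat_state, params, sh0 = 100,
                          fitted_temperatures_c = NULL) {
  stopifnot(inherits(params, "arrhenius_params"))
  structure(list(treatment = as.character(treatment),
                 heat_state = match.arg(heat_state, HEAT_STATES),
                 sh0 = sh0, params = params,
                 fitted_temperatures_c = fitted_temperatures_c),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %s/%s: SH = %g - %.5g * exp(-%.4f/(R*T)) * t  [%s]\n",
              x$treatment, x$heat_state, x$sh0, x$params$k0, x$params$ea,
              x$params$method))
  invisible(x)
}

#' Predict SH from a kinetic model
#'
#' SH(t, T) = sh0 - k0 exp(-Ea/(R T)) t, vectorized over time grids. The
#' temperature may be given in Celsius (`temperature_c`) or kelvin
#' (`temperature_k`); exactly one must be supplied.
#'
#' @param model a [kinetic_model].
#' @param time_days storage time(s), days >= 0.
#' @param temperature_c,temperature_k temperature (one of the two).
#' @return predicted SH, percent.
#' @export
predict_sh <- function(model, time_days, temperature_c = NULL,
                       temperature_k = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (is.null(temperature_k) == is.null(temperature_c)) {
    stop("supply exactly one of `temperature_c` or `temperature_k`",
         call. = FALSE)
  }
  if (is.null(temperature_k)) temperature_k <- celsius_to_kelvin(temperature_c)
  if (any(time_days < 0)) stop("time must be >= 0", call. = FALSE)
  model$sh0 - rate_at(model$params, temperature_k) * time_days
}

#' @export
predict.kinetic_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  predict_sh(object, df$time_days, temperature_c = df$temperature_c)
}
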