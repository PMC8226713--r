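#' Zero-order Arrhenius generating model
#'
#' Parameters of the decay process SH(t, T) = sh0 - k0 exp(-ea / (R T)) t
#' for one (treatment, heat_state) cell, on the percent scale.
#'
#' @param treatment treatment label.
#' @param heat_state `"raw"` or `"cooked"`.
#' @param k0 pre-exponential factor, day^-1 on the percent scale; > 0.
#' @param ea activation energy, kJ/mol; >= 0.
#' @param sh0 initial SH level, percent (default 100).
#' @return an object of class `generating_model`.
#' @export
generating_model <- function(treatment, heat_state, k0, ea, sh0 = 100) {
  heat_state <- match.arg(heat_state, HEAT_STATES)
  stopifnot(is.numeric(k0), length(k0) == 1, k0 > 0,
            is.numeric(ea), length(ea) == 1, ea >= 0,
            is.numeric(sh0), length(sh0) == 1, sh0 > 0)
  structure(list(treatment = as.character(treatment),
                 heat_state = heat_state,
                 k0 = k0, ea = ea, sh0 = sh0),
            class = "generating_model")
}

#' @export
print.generating_model <- function(x, ...) {
  cat(sprintf("<generating_model> %s/%s: SH = %g - %.4g * exp(-%.4g/(R*T)) * t\n",
              x$treatment, x$heat_state, x$sh0, x$k0, x$ea))
  invisible(x)
}

#' Storage-study simulation design
#'
#' Defaults emulate the chicken storage study: sampling at 4, 8 and 12 degC
#' daily for 13 days and at 16 and 20 degC daily for 5 days, triplicate
#' measurements, additive Gaussian noise with sd 2 on the percent scale.
#'
#' @param temperatures_c storage temperatures in degrees Celsius.
#' @param times_by_temperature named list mapping each temperature (as a
#'   character key) to its sampling days; every grid must include day 0.
#' @param replicates number of replicate measurements per time point.
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise, percent scale; >= 0.
#' @param seed integer RNG seed.
#' @param clamp_zero if `TRUE`, truncate simulated values at 0; default
#'   `FALSE` so that estimators see the linear model's full support.
#' @return an object of class `simulation_design`.
#' @export
study_design <- function(temperatures_c = c(4, 8, 12, 16, 20),
                         times_by_temperature = NULL,
                         replicates = 3,
                         noise_sd = 2,
                         seed = 1L,
                         clamp_zero = FALSE) {
  if (is.null(times_by_temperature)) {
    times_by_temperature <- lapply(temperatures_c, function(tc) {
      if (tc >= 16) 0:5 else 0:13
    })
    names(times_by_temperature) <- as.character(temperatures_c)
  }
  stopifnot(length(times_by_temperature) == length(temperatures_c),
            replicates >= 1, noise_sd >= 0)
  names(times_by_temperature) <- as.character(temperatures_c)
  for (tc in names(times_by_temperature)) {
    tt <- times_by_temperature[[tc]]
    if (any(tt < 0) || !any(tt == 0)) {
      stop("sampling days at ", tc, " degC must be >= 0 and include day 0",
           call. = FALSE)
    }
  }
  structure(list(temperatures_c = temperatures_c,
                 times_by_temperature = times_by_temperature,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 clamp_zero = isTRUE(clamp_zero)),
            class = "simulation_design")
}

#' Noise-free SH value under a generating model
#'
#' Evaluates SH(t, T) = sh0 - k0 exp(-ea / (R T)) t with R = 8.314e-3
#' kJ mol^-1 K^-1. Values are not clamped at zero.
#'
#' @param model a [generating_model].
#' @param time_days storage time(s), days >= 0.
#' @param temperature_k absolute temperature(s), kelvin > 0.
#' @return SH in percent (vectorized over `time_days`/`temperature_k`).
#' @export
sh_true <- function(model, time_days, temperature_k) {
  stopifnot(inherits(model, "generating_model"))
  if (any(temperature_k <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  if (any(time_days < 0)) stop("time must be >= 0", call. = FALSE)
  model$sh0 - model$k0 * exp(-model$ea / (R_GAS * temperature_k)) * time_days
}

simulate_series_impl <- function(model, design) {
  rows <- lapply(as.character(design$temperatures_c), function(tc) {
    times <- design$times_by_temperature[[tc]]
    tk <- celsius_to_kelvin(as.numeric(tc))
    grid <- expand.grid(replicate = seq_len(design$replicates),
                        time_days = times)
    truth <- sh_true(model, grid$time_days, tk)
    value <- truth + rnorm(nrow(grid), mean = 0, sd = design$noise_sd)
    if (design$clamp_zero) value <- pmax(value, 0)
    data.frame(treatment = model$treatment,
               heat_state = model$heat_state,
               temperature_c = as.numeric(tc),
               time_days = grid$time_days,
               replicate = grid$replicate,
               sh_value = value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate one (treatment, heat_state) time series
#'
#' Adds seeded, homoscedastic Gaussian noise to [sh_true] over the design's
#' full temperature/time/replicate grid. With `noise_sd = 0` the output
#' equals the noiseless model exactly; equal seeds give identical datasets.
#'
#' @param model a [generating_model].
#' @param design a [study_design].
#' @return an [sh_dataset] in percent units.
#' @export
simulate_series <- function(model, design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  sh_dataset(simulate_series_impl(model, design), unit = "percent",
             metadata = list(generator = "simulate_series",
                             seed = design$seed,
                             noise_sd = design$noise_sd))
}

#' Simulate a full factorial storage study
#'
#' Unions [simulate_series] over all model cells with a single shared seed
#' stream, so the whole study is reproducible from one seed. With the
#' default design and the 28 packaged reference models this yields
#' 28 * (3 * 14 + 2 * 6) * 3 = 4536 observations.
#'
#' @param models list of [generating_model]s with distinct
#'   (treatment, heat_state) cells.
#' @param design a [study_design].
#' @return an [sh_dataset] in percent units.
#' @export
simulate_study <- function(models = reference_models(),
                           design = study_design()) {
  stopifnot(inherits(design, "simulation_design"))
  cells <- vapply(models, function(m) paste(m$treatment, m$heat_state,
                                            sep = "/"), character(1))
  if (anyDuplicated(cells)) {
    stop("duplicate (treatment, heat_state) cell(s) in `models`: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "),
         call. = FALSE)
  }
  set.seed(design$seed)
  obs <- do.call(rbind, lapply(models, simulate_series_impl,
                               design = design))
  sh_dataset(obs, unit = "percent",
             metadata = list(generator = "simulate_study",
                             seed = design$seed,
                             noise_sd = design$noise_sd))
}

#' Packaged reference kinetic parameters
#'
#' The 28 published (k0, Ea) pairs for SH decay in minced raw and cooked
#' chicken meat with plant extracts (14 treatments x 2 heat states), shipped
#' as a plain-text table. These are the default generating parameters for
#' the synthetic study.
#'
#' @return data frame with columns `treatment`, `heat_state`, `k0` (day^-1),
#'   `ea` (kJ/mol), `r2` (reported determination coefficient).
#' @export
reference_parameter_table <- function() {
  path <- system.file("extdata", "reference_kinetic_params.csv",
                      package = "thiolkin", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reference generating models
#'
#' [reference_parameter_table] rows wrapped as [generating_model] objects
#' (sh0 = 100).
#'
#' @param treatment,heat_state optional filters; default all 28 cells.
#' @return list of [generating_model].
#' @export
reference_models <- function(treatment = NULL, heat_state = NULL) {
  tab <- reference_parameter_table()
  if (!is.null(treatment)) tab <- tab[tab$treatment %in% treatment, ]
  if (!is.null(heat_state)) tab <- tab[tab$heat_state %in% heat_state, ]
  if (nrow(tab) == 0) stop("no reference model matches the filter",
                           call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    generating_model(tab$treatment[i], tab$heat_state[i],
                     k0 = tab$k0[i], ea = tab$ea[i])
  })
}
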