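#' Simulate the reference storage study
#'
#' Convenience wrapper: the 28 packaged reference models over the default
#' factorial design (4/8/12 degC daily for 13 days, 16/20 degC daily for 5
#' days, triplicates), yielding 4536 observations.
#'
#' @param noise_sd measurement noise sd, percent (default 2).
#' @param seed RNG seed.
#' @param replicates replicate count (default 3).
#' @param clamp_zero truncate simulated values at 0 (default `FALSE`).
#' @return an [sh_dataset] in percent units.
#' @export
simulate_reference_study <- function(noise_sd = 2, seed = 1L,
                                     replicates = 3, clamp_zero = FALSE) {
  simulate_study(reference_models(),
                 study_design(noise_sd = noise_sd, seed = seed,
                              replicates = replicates,
                              clamp_zero = clamp_zero))
}

#' Fit kinetic models for every group in a study
#'
#' For each (treatment, heat_state) group: per-temperature zero-order fits
#' (excluding the hold-out temperature), the two-stage Arrhenius estimate,
#' and optionally the global Levenberg-Marquardt estimate initialized from
#' it. The two-stage estimate is the headline parameterization used to
#' build the returned [kinetic_model]s; pick `estimator = "global_lm"` to
#' use the global fit instead.
#'
#' @param dataset an [sh_dataset] in percent units.
#' @param holdout_temp_c hold-out temperature(s) in degC excluded from
#'   fitting (default 12); `NULL` fits all temperatures.
#' @param estimator `"both"`, `"two_stage"` or `"global_lm"`.
#' @param fix_intercept passed to [fit_zero_order].
#' @return list with `registry` (one row per group: both estimators'
#'   k0/Ea/r2), `models` (named list of [kinetic_model]s) and `isothermal`
#'   (per-group per-temperature rate-constant table).
#' @export
fit_study <- function(dataset, holdout_temp_c = 12,
                      estimator = c("both", "two_stage", "global_lm"),
                      fix_intercept = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dataset, "sh_dataset"))
  groups <- unique(as.data.frame(dataset)[c("treatment", "heat_state")])
  registry <- NULL
  iso_all <- NULL
  models <- list()
  for (i in seq_len(nrow(groups))) {
    tr <- groups$treatment[i]
    hs <- groups$heat_state[i]
    fits <- fit_all_temperatures(dataset, tr, hs,
                                 holdout_temp_c = holdout_temp_c,
                                 fix_intercept = fix_intercept)
    iso <- cbind(treatment = tr, heat_state = hs, isothermal_table(fits))
    iso_all <- rbind(iso_all, iso)
    two_stage <- if (estimator %in% c("both", "two_stage"))
      fit_arrhenius_two_stage(fits) else NULL
    global_lm <- if (estimator %in% c("both", "global_lm")) {
      grp <- dataset_group(dataset, tr, hs)
      keep <- if (is.null(holdout_temp_c)) rep(TRUE, nrow(grp)) else
        !grp$temperature_c %in% holdout_temp_c
      fit_arrhenius_global(as.data.frame(grp)[keep, , drop = FALSE],
                           init = two_stage)
    } else NULL
    headline <- if (estimator == "global_lm") global_lm else two_stage
    fitted_temps <- as.numeric(names(fits))
    models[[paste(tr, hs, sep = "/")]] <-
      kinetic_model(tr, hs, headline,
                    fitted_temperatures_c = fitted_temps)
    registry <- rbind(registry, data.frame(
      treatment = tr, heat_state = hs,
      k0_two_stage = if (is.null(two_stage)) NA_real_ else two_stage$k0,
      ea_two_stage = if (is.null(two_stage)) NA_real_ else two_stage$ea,
      r2_two_stage = if (is.null(two_stage)) NA_real_ else two_stage$r2,
      k0_global = if (is.null(global_lm)) NA_real_ else global_lm$k0,
      ea_global = if (is.null(global_lm)) NA_real_ else global_lm$ea,
      r2_global = if (is.null(global_lm)) NA_real_ else global_lm$r2,
      stringsAsFactors = FALSE))
  }
  list(registry = registry, models = models, isothermal = iso_all)
}

#' Externally validate fitted kinetic models on the hold-out temperature
#'
#' @param dataset the full study dataset (percent units).
#' @param models named list of [kinetic_model]s (from [fit_study]).
#' @param holdout_temp_c hold-out temperature(s), degC (default 12).
#' @return data frame with one row per group (`r2`, `adjusted_r2`, `rmse`,
#'   `n`) plus a pooled all-groups row; the per-group `fit_report`s are
#'   attached as the `"reports"` attribute.
#' @export
validate_study <- function(dataset, models, holdout_temp_c = 12) {
  stopifnot(inherits(dataset, "sh_dataset"))
  hold <- sh_dataset(
    as.data.frame(dataset)[dataset$temperature_c %in% holdout_temp_c, ,
                           drop = FALSE],
    unit = dataset_unit(dataset), metadata = attr(dataset, "metadata"))
  if (nrow(hold) == 0) {
    stop("no observations at hold-out temperature(s) ",
         paste(holdout_temp_c, collapse = ", "), " degC", call. = FALSE)
  }
  reports <- lapply(models, external_validate, holdout = hold)
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(group = nm, r2 = r$r2, adjusted_r2 = r$adjusted_r2,
               rmse = r$rmse, n = r$n, stringsAsFactors = FALSE)
  }))
  pooled_pairs <- do.call(rbind, lapply(reports, function(r) r$pairs))
  pooled <- goodness_of_fit(pooled_pairs$observed, pooled_pairs$predicted,
                            p = 2)
  rows <- rbind(rows, data.frame(group = "(pooled)", r2 = pooled$r2,
                                 adjusted_r2 = pooled$adjusted_r2,
                                 rmse = pooled$rmse, n = pooled$n,
                                 stringsAsFactors = FALSE))
  attr(rows, "reports") <- c(reports, list(`(pooled)` = pooled))
  rows
}
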