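# shared fixtures, built in code

# minimal well-formed observation table
obs_frame <- function(treatment = "control", heat_state = "raw",
                      temperature_c = 4, time_days = c(0, 1, 2),
                      replicate = 1L, sh_value = c(100, 95, 90)) {
  data.frame(treatment = treatment, heat_state = heat_state,
             temperature_c = temperature_c, time_days = time_days,
             replicate = replicate, sh_value = sh_value,
             stringsAsFactors = FALSE)
}

tiny_dataset <- function(...) sh_dataset(obs_frame(...), unit = "percent")

# exact zero-order series at one temperature: SH = intercept - k * t
exact_series <- function(k, times = 0:5, intercept = 100,
                         temperature_c = 4) {
  sh_dataset(obs_frame(temperature_c = temperature_c, time_days = times,
                       sh_value = intercept - k * times),
             unit = "percent")
}

# small compact design for simulation-heavy tests: 4 fit temperatures +
# the 12 degC hold-out, fewer sampling days than the full daily grid
compact_design <- function(noise_sd = 2, seed = 1L, replicates = 3) {
  study_design(
    temperatures_c = c(4, 8, 12, 16, 20),
    times_by_temperature = list(`4` = c(0, 3, 6, 9, 13),
                                `8` = c(0, 3, 6, 9, 13),
                                `12` = c(0, 3, 6, 9, 13),
                                `16` = c(0, 1, 3, 5),
                                `20` = c(0, 1, 3, 5)),
    replicates = replicates, noise_sd = noise_sd, seed = seed)
}
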