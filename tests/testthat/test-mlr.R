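# dataset with a known linear response surface and optional treatment
# offsets, generated with Ea = 0 models so the rate constant is
# temperature-independent and the true surface is exactly linear in time
null_mlr_dataset <- function(seed, noise_sd = 2, k = 3,
                             offsets = numeric(0),
                             treatments = TREATMENT_LEVELS) {
  models <- lapply(treatments, function(tr) {
    generating_model(tr, "raw", k0 = k, ea = 0)
  })
  ds <- simulate_study(models, compact_design(noise_sd = noise_sd,
                                              seed = seed))
  if (length(offsets) > 0) {
    df <- as.data.frame(ds)
    for (tr in names(offsets)) {
      sel <- df$treatment == tr
      df$sh_value[sel] <- df$sh_value[sel] + offsets[[tr]]
    }
    ds <- sh_dataset(df, unit = "percent")
  }
  ds
}

test_that("the design matrix dummy-codes treatments against control", {
  ds <- null_mlr_dataset(seed = 1)
  design <- build_design_matrix(ds, heat_state = "raw")
  expect_equal(ncol(design$x), 1 + 13 + 2)
  expect_length(design$treatments, 13)
  expect_false("treatment_control" %in% colnames(design$x))
  # control rows carry all-zero dummies
  ctrl <- design$x[as.data.frame(ds)$treatment == "control", ]
  expect_true(all(ctrl[, grep("^treatment_", colnames(design$x))] == 0))

  # a missing treatment drops its dummy with a warning
  sub <- sh_dataset(as.data.frame(ds)[ds$treatment != "thyme", ],
                    unit = "percent")
  expect_warning(d12 <- build_design_matrix(sub, heat_state = "raw"),
                 "thyme")
  expect_length(d12$treatments, 12)

  no_ctrl <- sh_dataset(as.data.frame(ds)[ds$treatment != "control", ],
                        unit = "percent")
  expect_error(build_design_matrix(no_ctrl, heat_state = "raw"), "absent")
})

test_that("fit_mlr matches the closed-form normal-equation solution", {
  ds <- null_mlr_dataset(seed = 2, noise_sd = 2,
                         treatments = c("control", "garlic", "clove"))
  design <- suppressWarnings(build_design_matrix(ds, heat_state = "raw"))
  fit <- fit_mlr(design)
  # brute-force oracle on the same <=6-column design
  x <- design$x
  y <- design$y
  beta <- unname(drop(solve(t(x) %*% x, t(x) %*% y)))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  resid <- y - x %*% beta
  s2 <- sum(resid^2) / (length(y) - ncol(x))
  se <- unname(sqrt(diag(solve(t(x) %*% x)) * s2))
  expect_equal(unname(fit$standard_errors), se, tolerance = 1e-10)
  tval <- beta / se
  expect_equal(unname(fit$t_statistics), tval, tolerance = 1e-10)
  expect_equal(unname(fit$p_values),
               2 * pt(abs(tval), length(y) - ncol(x), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("a noise-free linear response is recovered exactly", {
  ds <- null_mlr_dataset(seed = 3, noise_sd = 0, k = 4)
  design <- build_design_matrix(ds, heat_state = "raw")
  fit <- suppressWarnings(fit_mlr(design))  # perfect-fit summary warning
  # truth: intercept 100, time slope -4, temperature slope 0, dummies 0
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 100,
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[["time_days"]]), -4,
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[["temperature_c"]]), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(fit$coefficients[paste0("treatment_",
                                               design$treatments)])), 0,
               tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$see, 1e-6)
  # fitted + residuals reconstruct the response
  expect_equal(fitted(fit$lm_fit) + residuals(fit$lm_fit), design$y,
               ignore_attr = TRUE)
})

test_that("coefficients land within 3 SE of the generating values", {
  offsets <- c(garlic = 10, thyme = -8)
  ds <- null_mlr_dataset(seed = 4, noise_sd = 2, offsets = offsets)
  fit <- fit_mlr(build_design_matrix(ds, heat_state = "raw"))
  for (tr in TREATMENT_LEVELS[-1]) {
    truth <- if (tr %in% names(offsets)) offsets[[tr]] else 0
    est <- fit$coefficients[[paste0("treatment_", tr)]]
    se <- fit$standard_errors[[paste0("treatment_", tr)]]
    expect_lt(abs(est - truth), 3 * se)
  }
})

test_that("r2 is invariant to the reference level", {
  ds <- null_mlr_dataset(seed = 5, noise_sd = 2,
                         offsets = c(clove = 12))
  f_ctrl <- fit_mlr(build_design_matrix(ds, heat_state = "raw",
                                        reference = "control"))
  f_basil <- fit_mlr(build_design_matrix(ds, heat_state = "raw",
                                         reference = "basil"))
  expect_equal(f_ctrl$r2, f_basil$r2, tolerance = 1e-10)
  expect_equal(f_ctrl$see, f_basil$see, tolerance = 1e-10)
  # the clove-vs-control contrast is recoverable from the recoded fit
  expect_equal(
    f_ctrl$coefficients[["treatment_clove"]],
    f_basil$coefficients[["treatment_clove"]] -
      f_basil$coefficients[["treatment_control"]],
    tolerance = 1e-8)
})

test_that("compare_to_control flags the p <= 0.05 boundary inclusively", {
  fake <- structure(list(
    coefficients = c(`(Intercept)` = 100, treatment_basil = 2,
                     treatment_clove = -3, temperature_c = -1,
                     time_days = -5),
    standard_errors = c(1, 1, 1, 0.1, 0.1),
    t_statistics = c(100, 2, -3, -10, -50),
    p_values = c(`(Intercept)` = 0, treatment_basil = 0.049,
                 treatment_clove = 0.051, temperature_c = 0,
                 time_days = 0),
    heat_state = "raw", reference = "control", n = 100L
  ), class = "mlr_fit")
  tab <- compare_to_control(fake, alpha = 0.05)
  expect_identical(tab$significant[tab$treatment == "basil"], TRUE)
  expect_identical(tab$significant[tab$treatment == "clove"], FALSE)
  expect_identical(tab$effect[tab$treatment == "basil"], "antioxidant")
  expect_identical(tab$effect[tab$treatment == "clove"], "prooxidant")
})

test_that("a real treatment offset is flagged positive with high power", {
  hits <- vapply(1:20, function(s) {
    ds <- null_mlr_dataset(seed = 100 + s, noise_sd = 2,
                           offsets = c(nutmeg = 10))
    tab <- compare_to_control(fit_mlr(build_design_matrix(ds, "raw")))
    row <- tab[tab$treatment == "nutmeg", ]
    row$significant && row$estimate > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
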