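ann_fixture <- function(noise_sd = 2, seed = 11) {
  models <- reference_models(c("control", "garlic", "caraway", "basil"))
  ds <- simulate_study(models, compact_design(noise_sd = noise_sd,
                                              seed = seed))
  sh_dataset(as.data.frame(ds)[ds$temperature_c != 12, ],
             unit = "percent")
}

test_that("feature encoding one-hots categories and scales to [0, 1]", {
  ds <- simulate_reference_study(noise_sd = 0, seed = 1)
  enc <- encode_features(ds)
  # 14 treatment + 2 heat + time + temperature
  expect_equal(ncol(enc$x), 18)
  expect_true(all(rowSums(enc$x[, 1:14]) == 1))
  expect_true(all(rowSums(enc$x[, 15:16]) == 1))
  cr <- enc$x[ds$treatment == "control" & ds$heat_state == "raw", ]
  expect_true(all(cr[, "treatment_control"] == 1))
  expect_true(all(cr[, setdiff(colnames(cr)[1:14], "treatment_control")] == 0))
  expect_true(all(cr[, "heat_raw"] == 1 & cr[, "heat_cooked"] == 0))
  # min-max endpoints
  expect_equal(range(enc$x[, "time_scaled"]), c(0, 1))
  expect_equal(range(enc$x[, "temperature_scaled"]), c(0, 1))
  expect_equal(enc$x[ds$time_days == 0, "time_scaled"],
               rep(0, sum(ds$time_days == 0)), ignore_attr = TRUE)

  # reusing a scaling refuses unseen labels
  sub <- sh_dataset(as.data.frame(ds)[ds$treatment == "control", ],
                    unit = "percent")
  enc_sub <- encode_features(sub)
  expect_error(encode_features(ds, scaling = enc_sub$scaling), "unseen")
})

test_that("split_dataset produces exact disjoint 70:15:15 partitions", {
  ds <- simulate_reference_study(noise_sd = 0, seed = 1)
  base <- sh_dataset(as.data.frame(ds)[1:100, ], unit = "percent")
  sp <- split_dataset(base, seed = 3)
  expect_equal(vapply(sp, nrow, numeric(1)),
               c(train = 70, validation = 15, test = 15))

  # 101 rows: largest remainder gives the extra row to the train split
  base101 <- sh_dataset(as.data.frame(ds)[1:101, ], unit = "percent")
  sp101 <- split_dataset(base101, seed = 3)
  expect_equal(vapply(sp101, nrow, numeric(1)),
               c(train = 71, validation = 15, test = 15))

  # disjoint and exhaustive
  key <- function(d) paste(d$treatment, d$heat_state, d$temperature_c,
                           d$time_days, d$replicate)
  keys <- unlist(lapply(sp, key), use.names = FALSE)
  expect_equal(sort(keys), sort(key(base)))
  expect_equal(anyDuplicated(keys), 0)

  # seed reproducibility
  sp2 <- split_dataset(base, seed = 3)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))
  expect_error(split_dataset(base, ratios = c(60, 20, 10)), "100")
})

test_that("training is deterministic and a linear target is learnable", {
  ds <- ann_fixture(noise_sd = 0)
  enc <- encode_features(ds)
  # target is exactly linear in the features? SH is linear in t at fixed
  # (treatment, T); use a genuinely linear synthetic target instead
  y_lin <- drop(enc$x %*% seq(0.1, 1.8, length.out = ncol(enc$x))) * 50
  enc_lin <- list(x = enc$x, y = y_lin,
                  scaling = within(enc$scaling, sh <- range(y_lin)))
  spec <- mlp_spec(2, "tanh", "linear", max_iterations = 500, seed = 4)
  fit <- train_mlp(spec, enc_lin)
  expect_gte(fit$metrics$train[["r2"]], 0.999)

  # same spec + seed -> identical weights
  fit2 <- train_mlp(spec, enc_lin)
  expect_identical(fit$weights, fit2$weights)

  # zero iterations: predictions come from the initial weights
  spec0 <- mlp_spec(2, "tanh", "linear", max_iterations = 0, seed = 4)
  fit0 <- train_mlp(spec0, enc_lin)
  set.seed(4)
  expect_identical(fit0$weights,
                   runif(length(fit0$weights), -0.5, 0.5))
})

test_that("architecture search keeps the best five by validation error", {
  ds <- ann_fixture(noise_sd = 2)
  sp <- split_dataset(ds, seed = 7)
  ens <- search_architectures(
    sp$train, sp$validation, sp$test,
    hidden_sizes = c(4, 8, 12), hidden_activations = c("tanh", "logistic"),
    output_activations = "linear", seeds = 1L, n_keep = 5,
    max_iterations = 120)
  expect_s3_class(ens, "mlp_ensemble")
  expect_length(ens$members, 5)
  # ranked ascending by validation error
  expect_true(!is.unsorted(ens$summary$validation_error))
  # the best member fits the synthetic surface well
  expect_gt(max(ens$summary$test_accuracy), 0.9)
  # hold-out temperature was never seen
  expect_false(12 %in% ens$trained_temperatures_c)

  expect_error(
    search_architectures(sp$train, sp$validation,
                         hidden_sizes = 8, hidden_activations = "tanh",
                         n_keep = 5),
    "grid of 1 candidates")
})

test_that("duplicate candidates tie stably in grid order", {
  ds <- ann_fixture(noise_sd = 2)
  sp <- split_dataset(ds, seed = 7)
  ens <- search_architectures(
    sp$train, sp$validation,
    hidden_sizes = c(6, 6, 6, 6, 6), hidden_activations = "tanh",
    output_activations = "linear", seeds = 1L, n_keep = 5,
    max_iterations = 40)
  # identical specs + seed -> identical scores, kept in grid order
  expect_equal(length(unique(round(ens$summary$validation_error, 8))), 1)
  expect_equal(ens$summary$structure, rep(ens$summary$structure[1], 5))
})

test_that("ensemble prediction is the member mean and beats the worst member", {
  ds <- ann_fixture(noise_sd = 2)
  sp <- split_dataset(ds, seed = 9)
  ens <- search_architectures(
    sp$train, sp$validation, sp$test,
    hidden_sizes = c(4, 6, 8, 10, 12), hidden_activations = "tanh",
    output_activations = "linear", seeds = 1L, n_keep = 5,
    max_iterations = 80)
  enc <- encode_features(sp$test, scaling = ens$scaling)
  member_preds <- sapply(ens$members, predict_mlp, newdata = enc)
  expect_equal(ensemble_predict(ens, sp$test), rowMeans(member_preds),
               tolerance = 1e-12)
  # averaging a convex loss: ensemble rmse <= max member rmse
  rmse <- function(p) sqrt(mean((enc$y - p)^2))
  expect_lte(rmse(ensemble_predict(ens, sp$test)),
             max(apply(member_preds, 2, rmse)))

  # prediction is invariant to row order
  perm <- sample.int(nrow(sp$test))
  shuffled <- sh_dataset(as.data.frame(sp$test)[perm, ], unit = "percent")
  expect_equal(ensemble_predict(ens, shuffled),
               ensemble_predict(ens, sp$test)[perm], tolerance = 1e-12)
})

test_that("an ensemble survives a JSON round trip", {
  ds <- ann_fixture(noise_sd = 2)
  sp <- split_dataset(ds, seed = 5)
  ens <- search_architectures(
    sp$train, sp$validation,
    hidden_sizes = c(4, 6, 8, 10, 12), hidden_activations = "logistic",
    output_activations = "linear", seeds = 1L, n_keep = 5,
    max_iterations = 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(ensemble_predict(back, sp$validation),
               ensemble_predict(ens, sp$validation), tolerance = 1e-12)
  expect_equal(back$trained_temperatures_c, ens$trained_temperatures_c)
})
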