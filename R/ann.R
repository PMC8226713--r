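#' Encode storage conditions as MLP features
#'
#' One-hot blocks for treatment (14 indicators in the full design) and heat
#' state (2 indicators), plus min-max scaled storage time and temperature,
#' giving an 18-column matrix on the full design. The scaling (feature and
#' target ranges) is fitted on the data supplied and returned so that new
#' observations are encoded consistently at prediction time.
#'
#' @param dataset an [sh_dataset] in percent units.
#' @param scaling optional scaling object from a previous call; when given,
#'   its treatment levels and ranges are reused and unseen treatment labels
#'   are an error.
#' @return list with `x` (feature matrix), `y` (target SH, percent) and
#'   `scaling` (levels and min/max ranges).
#' @export
encode_features <- function(dataset, scaling = NULL) {
  df <- as.data.frame(dataset)
  stopifnot(all(c("treatment", "heat_state", "time_days",
                  "temperature_c", "sh_value") %in% names(df)))
  if (is.null(scaling)) {
    lev <- intersect(TREATMENT_LEVELS, unique(df$treatment))
    if (length(lev) == 0) lev <- sort(unique(df$treatment))
    scaling <- list(
      treatment_levels = lev,
      time = range(df$time_days),
      temperature = range(df$temperature_c),
      sh = range(df$sh_value)
    )
  }
  unknown <- setdiff(unique(df$treatment), scaling$treatment_levels)
  if (length(unknown) > 0) {
    stop("cannot encode unseen treatment label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  minmax <- function(v, r) {
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  treat <- matrix(0, nrow(df), length(scaling$treatment_levels),
                  dimnames = list(NULL, paste0("treatment_",
                                               scaling$treatment_levels)))
  treat[cbind(seq_len(nrow(df)),
              match(df$treatment, scaling$treatment_levels))] <- 1
  heat <- cbind(heat_raw = as.numeric(df$heat_state == "raw"),
                heat_cooked = as.numeric(df$heat_state == "cooked"))
  x <- cbind(treat, heat,
             time_scaled = minmax(df$time_days, scaling$time),
             temperature_scaled = minmax(df$temperature_c,
                                         scaling$temperature))
  list(x = x, y = df$sh_value, scaling = scaling)
}

#' MLP architecture and training specification
#'
#' One hidden layer; sum-of-squares loss; full-batch BFGS training.
#'
#' @param n_hidden hidden-layer width (>= 1).
#' @param hidden_activation `"tanh"`, `"logistic"` or `"exponential"`.
#' @param output_activation `"tanh"`, `"linear"` or `"logistic"`.
#' @param max_iterations BFGS iteration cap (default 300; 0 means no
#'   training, predictions come from the initial weights).
#' @param seed integer seed for the uniform(-0.5, 0.5) weight
#'   initialization.
#' @return an object of class `mlp_spec`.
#' @export
mlp_spec <- function(n_hidden, hidden_activation = "tanh",
                     output_activation = "linear",
                     max_iterations = 300, seed = 1L) {
  hidden_activation <- match.arg(hidden_activation,
                                 c("tanh", "logistic", "exponential"))
  output_activation <- match.arg(output_activation,
                                 c("tanh", "linear", "logistic"))
  stopifnot(n_hidden >= 1, max_iterations >= 0)
  structure(list(n_hidden = as.integer(n_hidden),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 error_function = "sum_of_squares",
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

activation_fn <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(z, a) 1 - a^2),
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(z, a) a * (1 - a)),
         exponential = list(f = exp, df = function(z, a) a),
         linear = list(f = identity, df = function(z, a) rep(1, length(a))))
}

n_mlp_weights <- function(n_in, n_hidden) {
  n_in * n_hidden + n_hidden + n_hidden + 1
}

unpack_weights <- function(w, n_in, n_hidden) {
  i <- 0
  w1 <- matrix(w[i + seq_len(n_in * n_hidden)], n_in, n_hidden)
  i <- i + n_in * n_hidden
  b1 <- w[i + seq_len(n_hidden)]; i <- i + n_hidden
  w2 <- w[i + seq_len(n_hidden)]; i <- i + n_hidden
  b2 <- w[i + 1]
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(w, x, spec) {
  p <- unpack_weights(w, ncol(x), spec$n_hidden)
  act_h <- activation_fn(spec$hidden_activation)
  act_o <- activation_fn(spec$output_activation)
  z1 <- sweep(x %*% p$w1, 2, p$b1, "+")
  h <- act_h$f(z1)
  z2 <- drop(h %*% p$w2) + p$b2
  list(z1 = z1, h = h, z2 = z2, out = act_o$f(z2))
}

mlp_loss_grad <- function(w, x, ys, spec) {
  p <- unpack_weights(w, ncol(x), spec$n_hidden)
  act_h <- activation_fn(spec$hidden_activation)
  act_o <- activation_fn(spec$output_activation)
  z1 <- sweep(x %*% p$w1, 2, p$b1, "+")
  h <- act_h$f(z1)
  z2 <- drop(h %*% p$w2) + p$b2
  out <- act_o$f(z2)
  err <- out - ys
  loss <- sum(err^2)
  d2 <- 2 * err * act_o$df(z2, out)
  gw2 <- drop(crossprod(h, d2))
  gb2 <- sum(d2)
  dh <- outer(d2, p$w2) * act_h$df(z1, h)
  gw1 <- crossprod(x, dh)
  gb1 <- colSums(dh)
  list(loss = loss, grad = c(as.vector(gw1), gb1, gw2, gb2))
}

#' Train one MLP regressor with BFGS
#'
#' Full-batch quasi-Newton (BFGS) minimization of the sum-of-squares error
#' on the scaled target (SH min-max scaled to [0, 1] using the training
#' scaling). Weights start uniform(-0.5, 0.5) from the spec's seed, so
#' training is deterministic given (spec, data).
#'
#' @param spec an [mlp_spec].
#' @param train encoded training data from [encode_features].
#' @param validation optional encoded validation data (same scaling).
#' @return an object of class `trained_mlp` carrying the weights, the
#'   scaling, and per-subset metrics (`sos` on the scaled target, `rmse`
#'   and `r2` on the percent scale).
#' @export
train_mlp <- function(spec, train, validation = NULL) {
  stopifnot(inherits(spec, "mlp_spec"), is.list(train),
            !is.null(train$x), !is.null(train$y))
  x <- train$x
  sh_range <- train$scaling$sh
  scale_y <- function(y) {
    if (diff(sh_range) == 0) rep(0, length(y)) else
      (y - sh_range[1]) / diff(sh_range)
  }
  unscale_y <- function(ys) ys * diff(sh_range) + sh_range[1]
  ys <- scale_y(train$y)
  nw <- n_mlp_weights(ncol(x), spec$n_hidden)
  set.seed(spec$seed)
  w0 <- runif(nw, -0.5, 0.5)
  big <- sqrt(.Machine$double.xmax)
  fn <- function(w) {
    v <- mlp_loss_grad(w, x, ys, spec)$loss
    if (!is.finite(v)) big else v
  }
  gr <- function(w) {
    g <- mlp_loss_grad(w, x, ys, spec)$grad
    g[!is.finite(g)] <- 0
    g
  }
  if (spec$max_iterations == 0) {
    w <- w0
    iterations <- 0L
  } else {
    opt <- optim(w0, fn, gr, method = "BFGS",
                 control = list(maxit = spec$max_iterations,
                                reltol = 1e-12))
    w <- opt$par
    iterations <- opt$counts[["gradient"]]
    if (!is.finite(opt$value) || opt$value >= big) {
      cond <- structure(
        class = c("thiolkin_training_failure", "error", "condition"),
        list(message = paste0("MLP training diverged (non-finite loss) ",
                              "after ", iterations, " gradient steps"),
             call = sys.call(-1)))
      stop(cond)
    }
  }
  model <- structure(list(spec = spec, weights = w, n_in = ncol(x),
                          n_weights = nw,
                          feature_names = colnames(x),
                          scaling = train$scaling,
                          iterations = iterations),
                     class = "trained_mlp")
  metrics_of <- function(enc) {
    pred <- predict_mlp(model, enc)
    c(sos = sum((scale_y(enc$y) - scale_y(pred))^2),
      rmse = sqrt(mean((enc$y - pred)^2)),
      r2 = goodness_of_fit(enc$y, pred)$r2)
  }
  model$metrics <- list(train = metrics_of(train))
  if (!is.null(validation)) model$metrics$validation <- metrics_of(validation)
  model
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf("<trained_mlp> %d-%d-1, %s/%s, %d weights, %d BFGS steps\n",
              x$n_in, x$spec$n_hidden, x$spec$hidden_activation,
              x$spec$output_activation, x$n_weights, x$iterations))
  if (!is.null(x$metrics$train)) {
    cat(sprintf("  train r2 = %.4f, rmse = %.3f\n",
                x$metrics$train[["r2"]], x$metrics$train[["rmse"]]))
  }
  invisible(x)
}

#' Predict SH from a trained MLP
#'
#' @param model a `trained_mlp`.
#' @param newdata an [sh_dataset] or an encoded list from
#'   [encode_features].
#' @return predicted SH on the percent scale.
#' @export
predict_mlp <- function(model, newdata) {
  stopifnot(inherits(model, "trained_mlp"))
  enc <- if (is.list(newdata) && !is.null(newdata$x)) newdata else
    encode_features(newdata, scaling = model$scaling)
  out <- mlp_forward(model$weights, enc$x, model$spec)$out
  sh_range <- model$scaling$sh
  out * diff(sh_range) + sh_range[1]
}

#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  predict_mlp(object, newdata)
}

#' Random 70:15:15 split into training, validation and test sets
#'
#' Disjoint random partition with largest-remainder rounding of the subset
#' sizes, reproducible by seed.
#'
#' @param dataset an [sh_dataset] with >= 10 rows.
#' @param ratios three percentages summing to 100 (default `c(70, 15, 15)`).
#' @param seed integer seed.
#' @return named list of `sh_dataset`s: `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, ratios = c(70, 15, 15), seed = 1L) {
  stopifnot(inherits(dataset, "sh_dataset"))
  if (length(ratios) != 3 || abs(sum(ratios) - 100) > 1e-8) {
    stop("`ratios` must be three percentages summing to 100", call. = FALSE)
  }
  n <- nrow(dataset)
  if (n < 10) stop("dataset too small to split (need >= 10 rows)",
                   call. = FALSE)
  exact <- n * ratios / 100
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    take <- order(exact - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[take] <- sizes[take] + 1
  }
  set.seed(seed)
  idx <- sample.int(n)
  bounds <- cumsum(sizes)
  pick <- function(i) {
    sh_dataset(as.data.frame(dataset)[sort(i), , drop = FALSE],
               unit = dataset_unit(dataset),
               metadata = attr(dataset, "metadata"))
  }
  list(train = pick(idx[seq_len(bounds[1])]),
       validation = pick(idx[(bounds[1] + 1):bounds[2]]),
       test = pick(idx[(bounds[2] + 1):bounds[3]]))
}

#' Architecture search returning the best-five ensemble
#'
#' Trains every candidate in the (hidden size x activation x seed) grid on
#' the training set, ranks candidates by validation sum-of-squares error
#' (ascending, ties broken by grid order), and retains the best five as an
#' ensemble. A summary table reports per-member training/validation/test
#' accuracy (r2 of observed vs predicted) and error.
#'
#' @param train,validation,test `sh_dataset` subsets (e.g. from
#'   [split_dataset]); `test` may be `NULL`.
#' @param hidden_sizes candidate hidden-layer widths (default
#'   `c(8, 12, 16, 20, 24, 30)`).
#' @param hidden_activations,output_activations candidate activations.
#' @param seeds weight-initialization seeds tried per architecture.
#' @param n_keep ensemble size (default 5).
#' @param max_iterations BFGS cap per candidate.
#' @return an object of class `mlp_ensemble` with fields `members`,
#'   `summary`, `scaling`, `n_weights` and `trained_temperatures_c`.
#' @export
search_architectures <- function(train, validation, test = NULL,
                                 hidden_sizes = c(8, 12, 16, 20, 24, 30),
                                 hidden_activations = c("tanh", "logistic"),
                                 output_activations = "linear",
                                 seeds = 1L, n_keep = 5,
                                 max_iterations = 300) {
  grid <- expand.grid(n_hidden = hidden_sizes,
                      hidden_activation = hidden_activations,
                      output_activation = output_activations,
                      seed = seeds, stringsAsFactors = FALSE)
  if (nrow(grid) < n_keep) {
    stop("cannot keep ", n_keep, " networks from a grid of ", nrow(grid),
         " candidates", call. = FALSE)
  }
  enc_train <- encode_features(train)
  enc_val <- encode_features(validation, scaling = enc_train$scaling)
  enc_test <- if (!is.null(test))
    encode_features(test, scaling = enc_train$scaling) else NULL
  candidates <- vector("list", nrow(grid))
  val_err <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- mlp_spec(grid$n_hidden[i], grid$hidden_activation[i],
                     grid$output_activation[i],
                     max_iterations = max_iterations, seed = grid$seed[i])
    fit <- tryCatch(train_mlp(spec, enc_train, enc_val),
                    thiolkin_training_failure = function(e) NULL)
    if (!is.null(fit)) {
      candidates[[i]] <- fit
      val_err[i] <- fit$metrics$validation[["sos"]]
    }
  }
  if (all(is.infinite(val_err))) {
    stop("architecture search failed: no candidate trained successfully",
         call. = FALSE)
  }
  keep <- order(val_err, seq_along(val_err))[seq_len(n_keep)]
  members <- candidates[keep]
  summary <- do.call(rbind, lapply(members, function(m) {
    test_metrics <- if (!is.null(enc_test)) {
      pred <- predict_mlp(m, enc_test)
      c(r2 = goodness_of_fit(enc_test$y, pred)$r2,
        rmse = sqrt(mean((enc_test$y - pred)^2)))
    } else c(r2 = NA_real_, rmse = NA_real_)
    data.frame(
      structure = sprintf("MLP %d-%d-1", m$n_in, m$spec$n_hidden),
      hidden_activation = m$spec$hidden_activation,
      output_activation = m$spec$output_activation,
      seed = m$spec$seed,
      iterations = m$iterations,
      training_accuracy = m$metrics$train[["r2"]],
      validation_accuracy = m$metrics$validation[["r2"]],
      test_accuracy = test_metrics[["r2"]],
      training_error = m$metrics$train[["sos"]],
      validation_error = m$metrics$validation[["sos"]],
      training_rmse = m$metrics$train[["rmse"]],
      test_rmse = test_metrics[["rmse"]],
      stringsAsFactors = FALSE)
  }))
  structure(list(members = members,
                 summary = summary,
                 scaling = enc_train$scaling,
                 n_weights = sum(vapply(members, function(m) m$n_weights,
                                        numeric(1))),
                 trained_temperatures_c =
                   sort(unique(c(train$temperature_c,
                                 validation$temperature_c)))),
            class = "mlp_ensemble")
}

#' @export
print.mlp_ensemble <- function(x, ...) {
  cat(sprintf("<mlp_ensemble> %d members\n", length(x$members)))
  print(x$summary[, c("structure", "hidden_activation", "output_activation",
                      "training_accuracy", "validation_accuracy")], ...)
  invisible(x)
}

#' Ensemble prediction: mean of the member networks
#'
#' @param ensemble an `mlp_ensemble`.
#' @param newdata an [sh_dataset] or encoded list.
#' @return predicted SH (%), the arithmetic mean of the member predictions.
#' @export
ensemble_predict <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "mlp_ensemble"))
  preds <- vapply(ensemble$members, predict_mlp,
                  numeric(if (is.list(newdata) && !is.null(newdata$x))
                    nrow(newdata$x) else nrow(newdata)),
                  newdata = newdata)
  rowMeans(as.matrix(preds))
}

#' @export
predict.mlp_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}

#' Serialize / restore an MLP ensemble as JSON
#'
#' Stores member specs, weights and the shared feature/target scaling in a
#' plain-text JSON document.
#'
#' @param ensemble an `mlp_ensemble`.
#' @param path output / input path.
#' @return `path` invisibly (write); an `mlp_ensemble` (read).
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "mlp_ensemble"))
  doc <- list(
    scaling = ensemble$scaling,
    trained_temperatures_c = ensemble$trained_temperatures_c,
    members = lapply(ensemble$members, function(m) {
      list(spec = unclass(m$spec), weights = m$weights, n_in = m$n_in,
           feature_names = m$feature_names, iterations = m$iterations)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  scaling <- list(
    treatment_levels = unlist(doc$scaling$treatment_levels),
    time = unlist(doc$scaling$time),
    temperature = unlist(doc$scaling$temperature),
    sh = unlist(doc$scaling$sh))
  members <- lapply(doc$members, function(m) {
    spec <- mlp_spec(m$spec$n_hidden, m$spec$hidden_activation,
                     m$spec$output_activation,
                     max_iterations = m$spec$max_iterations,
                     seed = m$spec$seed)
    structure(list(spec = spec,
                   weights = unlist(m$weights),
                   n_in = m$n_in,
                   n_weights = n_mlp_weights(m$n_in, spec$n_hidden),
                   feature_names = unlist(m$feature_names),
                   scaling = scaling,
                   iterations = m$iterations),
              class = "trained_mlp")
  })
  structure(list(members = members, summary = NULL, scaling = scaling,
                 n_weights = sum(vapply(members, function(m) m$n_weights,
                                        numeric(1))),
                 trained_temperatures_c =
                   unlist(doc$trained_temperatures_c)),
            class = "mlp_ensemble")
}
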