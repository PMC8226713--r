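#' @include thiolkin-package.R
NULL

DATASET_COLUMNS <- c(
  "treatment", "heat_state", "temperature_c", "time_days", "replicate",
  "sh_value"
)

#' Construct a storage-study dataset
#'
#' A thin S3 container around a long-format data frame of SH measurements.
#' One row is one measurement of thiol content in one sample at one storage
#' time. Values may be in raw assay units (nmol cysteine per mg protein) or
#' in percent of the day-0 value; the unit is carried as an attribute so
#' downstream fits can refuse un-normalized data.
#'
#' Negative SH values are permitted: the zero-order decay model is linear in
#' time and noiseless trajectories cross zero at long times, so estimators
#' are exercised on the model's actual support rather than a truncated one.
#'
#' @param observations data frame with columns `treatment`, `heat_state`,
#'   `temperature_c`, `time_days`, `replicate`, `sh_value`.
#' @param unit `"percent"` or `"raw_units"`.
#' @param metadata named list of free-form provenance (source file,
#'   generator seed, ...).
#' @return an object of class `sh_dataset` (a data frame).
#' @export
sh_dataset <- function(observations, unit = c("percent", "raw_units"),
                       metadata = list()) {
  unit <- match.arg(unit)
  if (!is.data.frame(observations)) {
    stop("`observations` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(DATASET_COLUMNS, names(observations))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs <- as.data.frame(observations)[DATASET_COLUMNS]
  obs$treatment <- as.character(obs$treatment)
  obs$heat_state <- as.character(obs$heat_state)
  for (col in c("temperature_c", "time_days", "sh_value")) {
    if (!is.numeric(obs[[col]])) {
      stop("column `", col, "` must be numeric", call. = FALSE)
    }
  }
  obs$replicate <- as.integer(obs$replicate)
  bad_heat <- setdiff(unique(obs$heat_state), HEAT_STATES)
  if (length(bad_heat) > 0) {
    stop("unknown heat_state value(s): ", paste(bad_heat, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(obs$time_days)) || any(obs$time_days < 0)) {
    stop("`time_days` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(obs$sh_value))) {
    stop("`sh_value` must be finite", call. = FALSE)
  }
  if (any(is.na(obs$replicate)) || any(obs$replicate < 1)) {
    stop("`replicate` must be a positive integer", call. = FALSE)
  }
  structure(obs,
            unit = unit,
            metadata = metadata,
            class = c("sh_dataset", "data.frame"))
}

#' @export
print.sh_dataset <- function(x, ...) {
  cat(sprintf(
    "<sh_dataset> %d observations, unit = %s\n", nrow(x), dataset_unit(x)))
  cat(sprintf("  treatments: %d | heat states: %s | temperatures (C): %s\n",
              length(unique(x$treatment)),
              paste(sort(unique(x$heat_state)), collapse = ", "),
              paste(sort(unique(x$temperature_c)), collapse = ", ")))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Unit tag of a dataset
#' @param dataset an `sh_dataset`.
#' @return `"percent"` or `"raw_units"`.
#' @export
dataset_unit <- function(dataset) {
  attr(dataset, "unit") %||% "percent"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

group_key <- function(dataset) {
  paste(dataset$treatment, dataset$heat_state, dataset$temperature_c,
        sep = "/")
}

#' Read a storage-study dataset from CSV
#'
#' Expects the canonical long-format header: `treatment`, `heat_state`,
#' `temperature_c`, `time_days`, `replicate`, `sh_value` (comma-separated,
#' UTF-8, `.` decimal separator).
#'
#' @param path path to a CSV file.
#' @param unit unit tag of the stored values, `"percent"` or `"raw_units"`.
#' @return an [sh_dataset].
#' @export
read_dataset <- function(path, unit = c("percent", "raw_units")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("malformed dataset file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("temperature_c", "time_days", "replicate", "sh_value")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric `", col, "` in ", path, " at data row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  sh_dataset(raw, unit = unit, metadata = list(source = path))
}

#' Write a storage-study dataset to CSV
#'
#' Writes the canonical column order at full precision so a read/write
#' round trip is lossless.
#'
#' @param dataset an [sh_dataset]; must be non-empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sh_dataset"))
  if (nrow(dataset) == 0) {
    stop("refusing to write an empty dataset", call. = FALSE)
  }
  out <- as.data.frame(dataset)[DATASET_COLUMNS]
  # full precision for bit-exact round trips
  for (col in c("temperature_c", "time_days", "sh_value")) {
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                         scientific = FALSE)
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write dataset to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Normalize SH values to percent of the day-0 baseline
#'
#' For every (treatment, heat_state, temperature) group, the baseline is the
#' arithmetic mean of all replicate measurements at `time_days == 0`; each
#' value becomes `100 * sh_value / baseline`. After normalization the day-0
#' group means equal 100 and within-group ratios are preserved exactly.
#' Normalization of data already in percent is idempotent whenever the
#' group baselines are already 100.
#'
#' @param dataset an [sh_dataset].
#' @return an [sh_dataset] in percent units.
#' @export
normalize_to_percent <- function(dataset) {
  stopifnot(inherits(dataset, "sh_dataset"))
  key <- group_key(dataset)
  baseline <- tapply(dataset$sh_value[dataset$time_days == 0],
                     key[dataset$time_days == 0], mean)
  missing <- setdiff(unique(key), names(baseline))
  if (length(missing) > 0) {
    stop("no day-0 baseline for group(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  if (any(baseline <= 0)) {
    stop("non-positive day-0 baseline for group(s): ",
         paste(names(baseline)[baseline <= 0], collapse = "; "),
         call. = FALSE)
  }
  obs <- as.data.frame(dataset)
  obs$sh_value <- 100 * obs$sh_value / as.vector(baseline[key])
  sh_dataset(obs, unit = "percent", metadata = attr(dataset, "metadata"))
}

#' Subset a dataset to one (treatment, heat_state) group
#'
#' @param dataset an [sh_dataset].
#' @param treatment treatment label.
#' @param heat_state `"raw"` or `"cooked"`.
#' @return an [sh_dataset] restricted to the group.
#' @export
dataset_group <- function(dataset, treatment, heat_state) {
  stopifnot(inherits(dataset, "sh_dataset"))
  sel <- dataset$treatment == treatment & dataset$heat_state == heat_state
  if (!any(sel)) {
    stop("group not present in dataset: ", treatment, "/", heat_state,
         call. = FALSE)
  }
  sh_dataset(as.data.frame(dataset)[sel, , drop = FALSE],
             unit = dataset_unit(dataset),
             metadata = attr(dataset, "metadata"))
}
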