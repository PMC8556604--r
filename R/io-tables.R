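# Delimited-text and JSON interchange: feature tables, classifier files,
# label sets, event lists.

.feature_cols <- c("current_density_norm", "range_within_pattern",
                   "mean_local_skewness", "lambda", "fit_error",
                   "alpha_band_power")

#' Construct a label set
#'
#' Per-component binary labels: `+1` = artifact (reject), `-1` = neural
#' (retain).
#'
#' @param labels numeric/integer vector with values in `{+1, -1}`.
#' @param source `"manual"` or `"automatic"`.
#' @return an object of class `eeg_labels`.
#' @export
label_set <- function(labels, source = c("manual", "automatic")) {
  source <- match.arg(source)
  labels <- as.integer(labels)
  if (length(labels) == 0 || !all(labels %in% c(-1L, 1L)))
    abort("labels must take values in {+1, -1}", "icaclean_label_error")
  structure(list(labels = labels, source = source), class = "eeg_labels")
}

as_label_vector <- function(x) {
  if (inherits(x, "eeg_labels")) x$labels else as.integer(x)
}

#' Write a feature table as TSV
#'
#' One row per component with a fixed column order: `component_id`, the six
#' features, and (when supplied) a final `label` column of +1/-1.
#'
#' @param features data.frame of feature values (columns
#'   `current_density_norm`, `range_within_pattern`, `mean_local_skewness`,
#'   `lambda`, `fit_error`, `alpha_band_power`; an optional `component_id`).
#' @param path output path.
#' @param labels optional [label_set()] (or +1/-1 vector), one per row.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, labels = NULL) {
  features <- as.data.frame(features)
  if (nrow(features) == 0)
    abort("feature table must be non-empty", "icaclean_io_error")
  missing_cols <- setdiff(.feature_cols, names(features))
  if (length(missing_cols))
    abort(paste("missing feature columns:",
                paste(missing_cols, collapse = ", ")), "icaclean_io_error")
  out <- data.frame(
    component_id = features$component_id %||% seq_len(nrow(features)),
    features[, .feature_cols, drop = FALSE]
  )
  if (!is.null(labels)) {
    lab <- as_label_vector(labels)
    if (length(lab) != nrow(out))
      abort("labels length must match the number of components",
            "icaclean_io_error")
    out$label <- lab
  }
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.9g", x))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write ", path), "icaclean_io_error")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return a data.frame; if a `label` column is present it carries the +1/-1
#'   labels.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "icaclean_io_error")
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

.classifier_fields <- c("w", "b", "feature_means", "feature_sds",
                        "alpha_band")

#' Save a trained classifier as JSON
#'
#' All stored numbers are written at full double precision so that a
#' save/load round trip is exact.
#'
#' @param clf an `eeg_classifier` from [train_component_classifier()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
serialize_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "eeg_classifier"))
  obj <- list(format = "icaclean_classifier", version = 1L,
              w = clf$w, b = clf$b,
              feature_means = clf$feature_means,
              feature_sds = clf$feature_sds,
              alpha_band = clf$alpha_band,
              feature_names = .feature_cols)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Load a classifier saved by [serialize_classifier()]
#'
#' @param path JSON path.
#' @return an `eeg_classifier`.
#' @export
deserialize_classifier <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "icaclean_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_fields <- setdiff(.classifier_fields, names(obj))
  if (length(missing_fields))
    abort(paste("classifier file missing field(s):",
                paste(missing_fields, collapse = ", ")),
          "icaclean_schema_error")
  new_classifier(w = as.numeric(obj$w), b = as.numeric(obj$b),
                 feature_means = as.numeric(obj$feature_means),
                 feature_sds = as.numeric(obj$feature_sds),
                 alpha_band = as.numeric(obj$alpha_band))
}

#' Read an event-latency list
#'
#' Two-column delimited text: `event_id`, `latency_s`. A header line is
#' detected automatically.
#'
#' @param path path to the file.
#' @return data.frame with columns `event_id` and `latency_s`.
#' @export
read_event_list <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", strsplit(first, "[\t ,]+")[[1]][2])
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("event_id", "latency_s")
  df$latency_s <- as.numeric(df$latency_s)
  df
}

#' Write an event-latency list
#' @param events data.frame with `event_id` and `latency_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_list <- function(events, path) {
  utils::write.table(events[, c("event_id", "latency_s")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
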