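# CSV/JSON interchange: lossless round trips with schema enforcement

cohort_columns <- function(schema) {
  c("lesion_id", "label", "age", names(schema))
}

#' Write a cohort to CSV (canonical columns)
#'
#' Header is fixed: `lesion_id,label,age,shape,orientation,margin,
#' lesion_boundary,echo_pattern,posterior_features`. Categories are written
#' as lexicon strings. The in-memory `histology` column is not part of the
#' interchange format and is dropped.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @param schema A [birads_schema()].
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, schema = birads_schema()) {
  cols <- cohort_columns(schema)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_feature_values <- function(df, schema, what = "cohort") {
  for (f in names(schema)) {
    bad <- !(df[[f]] %in% schema[[f]])
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unknown category in %s: lesion '%s', feature '%s', value '%s'",
                   what, df$lesion_id[i], f, df[[f]][i]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a cohort CSV
#'
#' Enforces the canonical header, label vocabulary, positive ages, and
#' schema category sets; errors name the offending lesion, feature and value.
#'
#' @param path CSV file written by [write_cohort_csv()].
#' @param schema A [birads_schema()].
#' @return A `birads_cohort` data frame.
#' @export
read_cohort_csv <- function(path, schema = birads_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  cols <- cohort_columns(schema)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_label <- !(df$label %in% c("malignant", "benign"))
  if (any(bad_label)) {
    stop(sprintf("invalid label '%s' for lesion '%s'",
                 df$label[which(bad_label)[1]],
                 df$lesion_id[which(bad_label)[1]]), call. = FALSE)
  }
  if (!is.numeric(df$age) || any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("ages must be positive numbers", call. = FALSE)
  }
  if (anyDuplicated(df$lesion_id)) stop("duplicate lesion_id in file", call. = FALSE)
  validate_feature_values(df, schema, what = "cohort")
  df <- df[, cols]
  class(df) <- c("birads_cohort", "data.frame")
  attr(df, "schema") <- schema
  df
}

#' Write an observation to CSV with a JSON sidecar
#'
#' The CSV holds `lesion_id` plus the six feature columns; the sidecar
#' `<path>.json` records the observation id, interval label, per-feature
#' fidelity and seed used to generate it.
#'
#' @param observation A `birads_observation`.
#' @param path Output CSV path.
#' @param schema A [birads_schema()].
#' @return `path`, invisibly.
#' @export
write_observation_csv <- function(observation, path, schema = birads_schema()) {
  cols <- c("lesion_id", names(schema))
  missing_cols <- setdiff(cols, names(observation))
  if (length(missing_cols)) {
    stop("observation lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(observation)[, cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  meta <- list(
    observation_id = attr(observation, "observation_id"),
    interval_label = attr(observation, "interval_label"),
    fidelity = as.list(attr(observation, "fidelity")),
    seed = attr(observation, "seed")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an observation CSV (and its JSON sidecar if present)
#'
#' @param path CSV path written by [write_observation_csv()].
#' @param schema A [birads_schema()].
#' @return A `birads_observation` data frame.
#' @export
read_observation_csv <- function(path, schema = birads_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  cols <- c("lesion_id", names(schema))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("observation file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_feature_values(df, schema, what = "observation")
  df <- df[, cols]
  class(df) <- c("birads_observation", "data.frame")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "observation_id") <- meta$observation_id
    attr(df, "interval_label") <- meta$interval_label
    attr(df, "fidelity") <- unlist(meta$fidelity)
    attr(df, "seed") <- meta$seed
  }
  df
}
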