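#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Canonical tidy schema shared by the generator, the session engine, and the
# analysis pipeline.
cohort_columns <- c(
  "participant_id", "session_id", "regime", "threshold", "rho",
  "est_C", "est_D", "est_L", "confidence", "action", "condition_order"
)

cohort_col_types <- readr::cols(
  participant_id = readr::col_integer(),
  session_id = readr::col_integer(),
  regime = readr::col_character(),
  threshold = readr::col_integer(),
  rho = readr::col_double(),
  est_C = readr::col_integer(),
  est_D = readr::col_integer(),
  est_L = readr::col_integer(),
  confidence = readr::col_integer(),
  action = readr::col_character(),
  condition_order = readr::col_integer(),
  .default = readr::col_guess()
)

#' Read and write cohort tables
#'
#' Cohort tables are comma-separated text with a header row, UTF-8 encoded,
#' "." decimal, one row per participant per condition, with the canonical
#' columns `participant_id`, `session_id`, `regime`, `threshold`, `rho`,
#' `est_C`, `est_D`, `est_L`, `confidence`, `action`, `condition_order`.
#' Externally deposited tables with other column names can be adapted with a
#' `mapping`, a named character vector from canonical names to the source's
#' column names; unmapped canonical columns that are absent are filled with
#' `NA`.
#'
#' @param path File path.
#' @param mapping Optional named character vector,
#'   `c(canonical = "source_name", ...)`.
#' @return `read_cohort()` returns a tibble in the canonical schema;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, mapping = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(mapping)) {
    stopifnot(!is.null(names(mapping)), all(names(mapping) %in% cohort_columns))
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src) > 0) {
      stop("mapped columns absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(mapping)) {
      raw[[canon]] <- raw[[mapping[[canon]]]]
    }
    raw <- raw[, intersect(cohort_columns, names(raw)), drop = FALSE]
  }
  missing_cols <- setdiff(
    c("participant_id", "regime", "threshold", "action"), names(raw)
  )
  if (length(missing_cols) > 0) {
    stop("cohort table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cohort_columns, names(raw))) raw[[col]] <- NA
  out <- raw[, cohort_columns, drop = FALSE]
  # re-parse through the canonical types
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  readr::write_csv(out, tmp)
  readr::read_csv(tmp, col_types = cohort_col_types)
}

#' @rdname read_cohort
#' @param records A cohort tibble.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read and write run configurations
#'
#' Run configurations are YAML key-value documents mirroring the arguments
#' of [cohort_config()]; they round-trip exactly (write then read gives an
#' equivalent configuration).
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [cohort_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, raw)
}

#' Write a machine-readable results document
#'
#' Serializes a (possibly nested) list of tibbles and scalars to JSON, with
#' run metadata (seed, package version, timestamp) alongside, so a full
#' analysis is reproducible from its output.
#'
#' @param results A named list of results (tibbles, vectors, scalars).
#' @param path Output path.
#' @param seed The seed(s) that produced the results, recorded as metadata.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, seed = NULL) {
  doc <- list(
    metadata = list(
      package = "volpgg",
      version = as.character(utils::packageVersion("volpgg")),
      seed = seed
    ),
    results = results
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
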