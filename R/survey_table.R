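#' Construct a survey table
#'
#' A `survey_table` is the universal exchange type of the package: a long
#' (tidy) table of abundance records, one row per (observation, taxon) pair,
#' tagged with an abundance unit and a survey label. Observations are water
#' samples, seine days, trawls, or pooled days depending on the survey; taxa
#' are species or lumped species groups. Absence means zero — explicit zero
#' rows are allowed but not required.
#'
#' @param records A data frame with columns `observation_id` (character),
#'   `taxon` (character), `value` (non-negative numeric), and optionally
#'   `date` (ISO-8601 string or Date), `group_key` (character, e.g. the
#'   seining day used for per-day grouping) and `volume_liters` (positive
#'   numeric, required when converting reads to copies per liter).
#' @param unit One of `"reads"`, `"copies_per_liter"`, `"catch_weight_kg"`,
#'   `"individuals"`. Uniform within a table.
#' @param survey_label Short label for the survey (e.g. `"sandy"`,
#'   `"rocky"`, `"estuary"`, `"winter"`).
#'
#' @return A tibble of class `survey_table` with attributes `unit` and
#'   `survey_label`, sorted by observation then taxon.
#' @examples
#' st <- survey_table(
#'   data.frame(
#'     observation_id = c("s1", "s1", "s2"),
#'     taxon = c("Micropogonias undulatus", "Paralichthys dentatus",
#'               "Micropogonias undulatus"),
#'     value = c(120, 30, 80)
#'   ),
#'   unit = "reads", survey_label = "estuary"
#' )
#' st
#' @export
survey_table <- function(records, unit, survey_label = "survey") {
  unit <- match.arg(unit, .edds_units)
  records <- tibble::as_tibble(records)
  attr(records, "out.attrs") <- NULL
  required <- c("observation_id", "taxon", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("survey_table records lack column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "edds_schema_error")
  }
  records$observation_id <- as.character(records$observation_id)
  records$taxon <- as.character(records$taxon)
  records$value <- as.numeric(records$value)
  # dates kept as ISO-8601 strings so round-trips are exact
  if ("date" %in% names(records)) records$date <- as.character(records$date)
  out <- dplyr::arrange(records, .data$observation_id, .data$taxon)
  out <- structure(out,
                   unit = unit,
                   survey_label = as.character(survey_label),
                   class = c("survey_table", class(tibble::tibble())))
  validate_survey_table(out)
}

#' Validate a survey table's invariants
#'
#' Checks for duplicate (observation, taxon) pairs, negative values, and a
#' recognised unit. Called by every constructor and reader; exported so
#' pipelines that manipulate the underlying tibble directly can re-validate.
#'
#' @param x A `survey_table`.
#' @return `x`, invisibly unchanged, or an error of class
#'   `edds_schema_error`.
#' @export
validate_survey_table <- function(x) {
  if (!inherits(x, "survey_table")) {
    abort("not a survey_table", class = "edds_schema_error")
  }
  if (!(attr(x, "unit") %in% .edds_units)) {
    abort(paste0("unknown abundance unit: ", attr(x, "unit")),
          class = "edds_schema_error")
  }
  key <- paste(x$observation_id, x$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE]
    abort(paste0("duplicate (observation_id, taxon) pair(s), e.g. (",
                 dup$observation_id[1], ", ", dup$taxon[1], ")"),
          class = "edds_schema_error")
  }
  if (any(is.na(x$value)) || any(x$value < 0)) {
    abort("values must be non-negative and non-missing",
          class = "edds_schema_error")
  }
  if ("volume_liters" %in% names(x)) {
    bad <- !is.na(x$volume_liters) & x$volume_liters <= 0
    if (any(bad)) {
      abort("volume_liters must be positive where present",
            class = "edds_schema_error")
    }
  }
  invisible(x)
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %s [%s]: %d records, %d observations, %d taxa\n",
              attr(x, "survey_label"), attr(x, "unit"), nrow(x),
              length(unique(x$observation_id)), length(unique(x$taxon))))
  NextMethod()
}

#' Abundance unit of a survey table
#' @param x A `survey_table`.
#' @return The unit string.
#' @export
st_unit <- function(x) attr(x, "unit")

#' Survey label of a survey table
#' @param x A `survey_table`.
#' @return The survey label string.
#' @export
st_label <- function(x) attr(x, "survey_label")

#' Read a survey table from CSV
#'
#' The CSV must have a header with columns `observation_id`, `taxon`,
#' `value`, and may carry `date`, `group_key`, `volume_liters`. This is the
#' canonical interchange schema; supplementary spreadsheets are ingested by
#' exporting each sheet to this layout.
#'
#' @param path CSV file path.
#' @inheritParams survey_table
#' @return A validated `survey_table`.
#' @export
read_survey_table <- function(path, unit, survey_label = "survey") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  survey_table(df, unit = unit, survey_label = survey_label)
}

#' Write a survey table to CSV
#'
#' Rows are emitted sorted by `observation_id` then `taxon`, so output is
#' byte-deterministic for a given table.
#'
#' @param x A `survey_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  validate_survey_table(x)
  out <- dplyr::arrange(tibble::as_tibble(x), .data$observation_id, .data$taxon)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Convert a survey table to a wide observation-by-taxon matrix
#'
#' A convenience export: rows are observations, columns taxa, absences
#' filled with 0. Row and column order is alphabetical (deterministic).
#'
#' @param x A `survey_table`.
#' @return A numeric matrix with observation rownames and taxon colnames.
#' @export
st_as_matrix <- function(x) {
  validate_survey_table(x)
  obs <- sort(unique(x$observation_id))
  taxa <- sort(unique(x$taxon))
  m <- matrix(0, nrow = length(obs), ncol = length(taxa),
              dimnames = list(obs, taxa))
  m[cbind(match(x$observation_id, obs), match(x$taxon, taxa))] <- x$value
  m
}

#' Build a survey table from an observation-by-taxon matrix
#'
#' Inverse of [st_as_matrix()]; zero cells are dropped (absence = 0).
#'
#' @param m Numeric matrix, rows = observations, columns = taxa.
#' @inheritParams survey_table
#' @param keep_zeros Keep explicit zero cells? Default `FALSE`.
#' @param volumes Optional named vector of filtered liters per observation,
#'   stored as a `volume_liters` column.
#' @return A `survey_table`.
#' @export
st_from_matrix <- function(m, unit, survey_label = "survey",
                           keep_zeros = FALSE, volumes = NULL) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must have observation rownames and taxon colnames",
          class = "edds_schema_error")
  }
  df <- tibble::tibble(
    observation_id = rep(rownames(m), times = ncol(m)),
    taxon = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  if (!keep_zeros) df <- df[df$value != 0, , drop = FALSE]
  if (!is.null(volumes)) {
    df$volume_liters <- unname(volumes[df$observation_id])
  }
  survey_table(df, unit = unit, survey_label = survey_label)
}

#' Write a pipeline result to disk
#'
#' Dispatches on result type: per-observation criteria tables and ranked
#' abundances become CSV (deterministic row order); nested summaries (lists)
#' become JSON. Criteria CSVs carry the columns `observation_id`,
#' `prop_same`, `prop_shared`, `prop_other_total`, `prop_non_edds`,
#' `dominance`, `classified`, `predicted_label`.
#'
#' @param x A result object (`criteria_result` table, `ranked_abundance`,
#'   `survey_table`, or a plain list summary).
#' @param path Output path (`.csv` or `.json` chosen by the caller).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  UseMethod("write_results")
}

#' @export
write_results.survey_table <- function(x, path) write_survey_table(x, path)

#' @export
write_results.ranked_abundance <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @export
write_results.criteria_result <- function(x, path) {
  cols <- c("observation_id", "prop_same", "prop_shared", "prop_other_total",
            "prop_non_edds", "dominance", "classified", "predicted_label")
  out <- tibble::as_tibble(x)[, cols, drop = FALSE]
  out <- dplyr::arrange(out, .data$observation_id)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
write_results.list <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path) {
  out <- tibble::as_tibble(x)
  if ("observation_id" %in% names(out)) {
    ord <- c("observation_id", intersect("taxon", names(out)))
    out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(ord)))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
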