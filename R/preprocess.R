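#' Read a per-library read-count matrix
#'
#' A read matrix holds raw metabarcoding read counts, libraries (water
#' samples) as rows and taxa — including the spike-in standard — as columns.
#' Wide CSVs are laid out taxa-by-libraries (first column = taxon name) and
#' transposed on read; long CSVs use the `observation_id,taxon,value`
#' schema.
#'
#' @param path CSV path.
#' @param layout `"wide"` (rows = taxa, columns = libraries) or `"long"`.
#' @return Integer matrix, libraries x taxa.
#' @export
read_read_matrix <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "wide") {
    taxa <- as.character(df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- taxa
  } else {
    st <- survey_table(df, unit = "reads")
    m <- st_as_matrix(st)
  }
  storage.mode(m) <- "double"
  validate_read_matrix(m)
  m
}

validate_read_matrix <- function(reads) {
  if (!is.matrix(reads) || is.null(rownames(reads)) || is.null(colnames(reads))) {
    abort("read matrix needs library rownames and taxon colnames",
          class = "edds_schema_error")
  }
  if (any(is.na(reads)) || any(reads < 0) || any(reads != round(reads))) {
    abort("read counts must be non-negative integers",
          class = "edds_schema_error")
  }
  invisible(reads)
}

#' Remove tag-jump (index-hopping) detections
#'
#' Multiplexed sequencing lets a small fraction of reads acquire the wrong
#' library index, planting false low-count detections of taxa that are
#' abundant elsewhere in the run. The filter zeroes, per taxon, any library
#' count strictly below `threshold` times that taxon's total reads across
#' all libraries in the run; counts at or above the cut are untouched.
#' Totals are taken from the original matrix in a single pass — the filter
#' is not iterated, and it is idempotent anyway because every surviving cell
#' already meets the cut against the (no larger) post-filter totals.
#'
#' @param reads Libraries x taxa count matrix for one sequencing run.
#' @param threshold Fraction of the per-taxon run total below which a
#'   detection is considered a tag jump (default 0.001, i.e. 0.1%).
#' @return Filtered matrix, same shape.
#' @export
filter_tag_jumps <- function(reads, threshold = 0.001) {
  validate_read_matrix(reads)
  stopifnot(threshold > 0, threshold < 1)
  totals <- colSums(reads)
  cut <- matrix(threshold * totals, nrow = nrow(reads), ncol = ncol(reads),
                byrow = TRUE)
  out <- reads
  out[reads < cut] <- 0
  out
}

#' Convert reads to eDNA copies per liter via the internal standard
#'
#' Each library is spiked before PCR with a known copy number of a standard
#' amplicon (ostrich 12S, sharing the fish primer sites). Absolute copy
#' estimates follow by proportion, then are divided by the filtered water
#' volume:
#' \deqn{copies/L(i,t) = reads(i,t) / reads(i, std) \times spike\_copies / volume_i}
#' Within a library the result is proportional to reads across taxa, so all
#' share-based results downstream are invariant to `spike_copies`.
#'
#' @param reads Libraries x taxa count matrix including the standard column.
#' @param standard_taxon Column name of the spike-in standard.
#' @param spike_copies Copies of standard added per reaction.
#' @param volumes Named vector, filtered liters per library. Defaults to
#'   1 L for every library (the common whole-bottle case).
#' @param survey_label Label for the resulting table.
#' @return A `survey_table` in `copies_per_liter`, standard row removed,
#'   zero cells dropped, volumes carried in `volume_liters`.
#' @export
reads_to_copies <- function(reads, standard_taxon = "Struthio camelus",
                            spike_copies = 1000, volumes = NULL,
                            survey_label = "survey") {
  validate_read_matrix(reads)
  if (!(standard_taxon %in% colnames(reads))) {
    abort(paste0("standard taxon '", standard_taxon, "' absent from matrix"),
          class = "edds_quantification_error")
  }
  std <- reads[, standard_taxon]
  if (any(std == 0)) {
    abort(paste0("standard reads are zero in library(ies): ",
                 paste(rownames(reads)[std == 0], collapse = ", ")),
          class = "edds_quantification_error")
  }
  if (is.null(volumes)) {
    volumes <- setNames(rep(1, nrow(reads)), rownames(reads))
  }
  missing_vol <- setdiff(rownames(reads), names(volumes))
  if (length(missing_vol) > 0 || any(is.na(volumes[rownames(reads)]))) {
    abort(paste0("missing filtered volume for library(ies): ",
                 paste(missing_vol, collapse = ", ")),
          class = "edds_quantification_error")
  }
  vol <- volumes[rownames(reads)]
  if (any(vol <= 0)) {
    abort("filtered volumes must be positive",
          class = "edds_quantification_error")
  }
  fish <- reads[, setdiff(colnames(reads), standard_taxon), drop = FALSE]
  copies <- fish / std * spike_copies / vol
  st_from_matrix(copies, unit = "copies_per_liter",
                 survey_label = survey_label, volumes = vol)
}

#' Lump indistinguishable taxa and drop excluded ones
#'
#' Renames taxa through the lump map (summing values that land on the same
#' lumped label within an observation) and removes every taxon in the
#' exclusion set. Exclusion happens here, before any proportion is formed,
#' so downstream denominators contain only retained (bony, marine) fish.
#' Total abundance is conserved up to the excluded taxa's total, and the
#' operation is idempotent.
#'
#' @param table A `survey_table`.
#' @param maps A [taxon_maps()].
#' @return A `survey_table` with the same unit and label.
#' @export
lump_and_exclude <- function(table, maps) {
  validate_survey_table(table)
  stopifnot(inherits(maps, "taxon_maps"))
  df <- tibble::as_tibble(table)
  df <- df[!(df$taxon %in% maps$exclusion_set), , drop = FALSE]
  hit <- df$taxon %in% names(maps$lump_map)
  df$taxon[hit] <- unname(maps$lump_map[df$taxon[hit]])
  extra <- intersect(c("date", "group_key", "volume_liters"), names(df))
  df <- dplyr::group_by(df, .data$observation_id, .data$taxon)
  df <- dplyr::summarise(
    df,
    value = sum(.data$value),
    dplyr::across(dplyr::all_of(extra), dplyr::first),
    .groups = "drop"
  )
  survey_table(df, unit = st_unit(table), survey_label = st_label(table))
}

#' Group eDNA and catch observations by day
#'
#' Seine-day protocol: individual hauls can be empty and water samples
#' several per day, so both tables are collapsed to one observation per day.
#' Catch: individuals summed per day, divided by the number of hauls that
#' day (individuals per haul). eDNA: day-level copies/L obtained by
#' volume-weighted pooling — total raw copies across the day's samples
#' divided by total filtered liters (`edna_agg = "volume_weighted"`, the
#' default), or alternatively the unweighted mean of per-sample copies/L
#' (`"sample_mean"`). Days present in only one table are retained with a
#' warning.
#'
#' @param edna `survey_table` in `copies_per_liter` with `group_key` (day)
#'   and `volume_liters` set on every record.
#' @param catch `survey_table` in `individuals` (or `catch_weight_kg`) with
#'   `group_key` set.
#' @param hauls_per_day Named vector: hauls per day key; all >= 1.
#' @param edna_agg Day-level eDNA aggregation rule (see above).
#' @return List with elements `edna` and `catch`, observation ids replaced
#'   by day keys.
#' @export
group_by_day <- function(edna, catch, hauls_per_day,
                         edna_agg = c("volume_weighted", "sample_mean")) {
  edna_agg <- match.arg(edna_agg)
  validate_survey_table(edna)
  validate_survey_table(catch)
  if (st_unit(edna) != "copies_per_liter") {
    abort("edna table must be in copies_per_liter", class = "edds_schema_error")
  }
  for (tb in list(edna, catch)) {
    if (!("group_key" %in% names(tb)) || any(is.na(tb$group_key))) {
      abort("every observation needs a group_key (day)",
            class = "edds_schema_error")
    }
  }
  if (!("volume_liters" %in% names(edna)) || any(is.na(edna$volume_liters))) {
    abort("edna observations need volume_liters", class = "edds_schema_error")
  }
  edna_days <- unique(edna$group_key)
  catch_days <- unique(catch$group_key)
  lonely <- c(setdiff(edna_days, catch_days), setdiff(catch_days, edna_days))
  if (length(lonely) > 0) {
    warn(paste0("day(s) present in only one table: ",
                paste(sort(lonely), collapse = ", ")))
  }
  missing_h <- setdiff(catch_days, names(hauls_per_day))
  if (length(missing_h) > 0 || any(hauls_per_day < 1)) {
    abort("hauls_per_day must cover every catch day and be >= 1",
          class = "edds_schema_error")
  }

  ed <- tibble::as_tibble(edna)
  # per-sample volumes: one volume per observation, counted once per sample
  sample_vol <- dplyr::distinct(ed, .data$group_key, .data$observation_id,
                                .data$volume_liters)
  day_vol <- dplyr::summarise(dplyr::group_by(sample_vol, .data$group_key),
                              liters = sum(.data$volume_liters),
                              n_samples = dplyr::n(), .groups = "drop")
  ed$raw_copies <- ed$value * ed$volume_liters
  if (edna_agg == "volume_weighted") {
    ed2 <- dplyr::summarise(dplyr::group_by(ed, .data$group_key, .data$taxon),
                            raw = sum(.data$raw_copies), .groups = "drop")
    ed2 <- dplyr::left_join(ed2, day_vol, by = "group_key")
    ed2$value <- ed2$raw / ed2$liters
  } else {
    ed2 <- dplyr::summarise(dplyr::group_by(ed, .data$group_key, .data$taxon),
                            value = sum(.data$value), .groups = "drop")
    ed2 <- dplyr::left_join(ed2, day_vol, by = "group_key")
    ed2$value <- ed2$value / ed2$n_samples
  }
  edna_out <- survey_table(
    tibble::tibble(observation_id = ed2$group_key, taxon = ed2$taxon,
                   value = ed2$value,
                   volume_liters = ed2$liters),
    unit = "copies_per_liter", survey_label = st_label(edna)
  )

  ct <- tibble::as_tibble(catch)
  ct2 <- dplyr::summarise(dplyr::group_by(ct, .data$group_key, .data$taxon),
                          value = sum(.data$value), .groups = "drop")
  ct2$value <- ct2$value / unname(hauls_per_day[ct2$group_key])
  catch_out <- survey_table(
    tibble::tibble(observation_id = ct2$group_key, taxon = ct2$taxon,
                   value = ct2$value),
    unit = st_unit(catch), survey_label = st_label(catch)
  )
  list(edna = edna_out, catch = catch_out)
}
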