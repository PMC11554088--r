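#' Rank-abundance distribution of a survey
#'
#' Aggregates abundance per taxon over all observations (sum by default;
#' mean per observation available) and ranks taxa by decreasing aggregate
#' abundance — the survey's species abundance distribution. Coastal fish
#' surveys show the classic hollow curve: a few very common species and a
#' long tail of rare ones. Ties are broken by taxon name ascending so the
#' ranking is deterministic.
#'
#' @param table A `survey_table` with positive total abundance.
#' @param agg `"sum"` (aggregate abundance over the survey, the default) or
#'   `"mean"` (mean per observation; identical ranking when all taxa appear
#'   under the same observation count denominator).
#' @return A tibble of class `ranked_abundance` with columns `taxon`,
#'   `value`, `share`, `cumulative_share`, ordered by rank; attributes
#'   `survey_label`, `unit`, `n_observations`.
#' @export
rank_abundance <- function(table, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  validate_survey_table(table)
  df <- tibble::as_tibble(table)
  if (nrow(df) == 0 || sum(df$value) <= 0) {
    abort("survey has no positive abundance to rank",
          class = "edds_empty_error")
  }
  n_obs <- length(unique(df$observation_id))
  agg_tab <- dplyr::summarise(dplyr::group_by(df, .data$taxon),
                              value = sum(.data$value), .groups = "drop")
  if (agg == "mean") agg_tab$value <- agg_tab$value / n_obs
  agg_tab <- agg_tab[order(-agg_tab$value, agg_tab$taxon), , drop = FALSE]
  agg_tab$share <- agg_tab$value / sum(agg_tab$value)
  agg_tab$cumulative_share <- cumsum(agg_tab$share)
  structure(agg_tab,
            survey_label = st_label(table),
            unit = st_unit(table),
            n_observations = n_obs,
            class = c("ranked_abundance", class(tibble::tibble())))
}

#' @export
print.ranked_abundance <- function(x, ...) {
  cat(sprintf("<ranked_abundance> %s [%s]: %d taxa over %d observations\n",
              attr(x, "survey_label"), attr(x, "unit"), nrow(x),
              attr(x, "n_observations")))
  NextMethod()
}

#' Select the dominant taxa of a ranked abundance
#'
#' Three heuristics for "the common species": the protocol default takes
#' the `top_n` most abundant taxa (the eDDS); `"cumulative_share"` takes
#' the shortest rank-ordered prefix whose cumulative share strictly exceeds
#' `cumulative_threshold` (default 90% of total abundance); `"min_share"`
#' takes every taxon whose individual share strictly exceeds
#' `min_share_threshold` (default 1%). A tie in abundance spanning the
#' `top_n` boundary is resolved by taxon name and flagged with a warning,
#' since the selected set then depends on the tie-break.
#'
#' @param ranked A `ranked_abundance`.
#' @param heuristic One of `"top_n"`, `"cumulative_share"`, `"min_share"`.
#' @param config A [protocol_config()] supplying `top_n` and the two
#'   thresholds.
#' @return Character vector of dominant taxa (in rank order).
#' @export
select_dominants <- function(ranked, heuristic = NULL,
                             config = protocol_config()) {
  stopifnot(inherits(ranked, "ranked_abundance"))
  if (is.null(heuristic)) heuristic <- config$dominance_heuristic
  heuristic <- match.arg(heuristic,
                         c("top_n", "cumulative_share", "min_share"))
  if (heuristic == "top_n") {
    k <- min(config$top_n, nrow(ranked))
    if (k < nrow(ranked) && ranked$value[k] == ranked$value[k + 1]) {
      warn(sprintf(
        "abundance tie spans the top-%d boundary (taxa '%s' and '%s'); %s",
        config$top_n, ranked$taxon[k], ranked$taxon[k + 1],
        "selection resolved by taxon name"))
    }
    return(ranked$taxon[seq_len(k)])
  }
  if (heuristic == "cumulative_share") {
    k <- match(TRUE, ranked$cumulative_share > config$cumulative_threshold,
               nomatch = nrow(ranked))
    return(ranked$taxon[seq_len(k)])
  }
  ranked$taxon[ranked$share > config$min_share_threshold]
}

#' Build an eDDS profile from per-survey dominant sets
#'
#' Every taxon dominant in exactly one survey is labelled with that
#' survey's label (habitat- or season-associated); a taxon dominant in two
#' or more surveys is `"shared"`. Taxa outside every dominant set are absent
#' from the profile — non-eDDS by omission. A profile is a frozen object:
#' applying it to new data never mutates it, so later datasets can be
#' classified without re-analysing the original surveys.
#'
#' @param dominant_sets Named list (>= 2 unique labels) of character
#'   vectors of dominant taxa, e.g. the output of [select_dominants()] per
#'   survey.
#' @return An object of class `edds_profile` with fields `category_of`
#'   (named character: taxon -> label or `"shared"`), `labels`, and
#'   `provenance` (the input sets).
#' @examples
#' build_profile(list(sandy = c("a", "b", "s"), rocky = c("c", "s"),
#'                    estuary = c("d", "s")))
#' @export
build_profile <- function(dominant_sets) {
  labels <- names(dominant_sets)
  if (is.null(labels) || length(dominant_sets) < 2) {
    abort("need at least two labelled dominant sets",
          class = "edds_config_error")
  }
  if (anyDuplicated(labels) || any(labels == "") || "shared" %in% labels) {
    abort("labels must be unique, non-empty, and not 'shared'",
          class = "edds_config_error")
  }
  all_taxa <- sort(unique(unlist(dominant_sets)))
  counts <- vapply(all_taxa, function(t) {
    sum(vapply(dominant_sets, function(s) t %in% s, logical(1)))
  }, integer(1))
  category <- vapply(all_taxa, function(t) {
    if (counts[[t]] >= 2L) "shared"
    else labels[vapply(dominant_sets, function(s) t %in% s, logical(1))]
  }, character(1))
  structure(list(category_of = category,
                 labels = labels,
                 provenance = lapply(dominant_sets, as.character)),
            class = "edds_profile")
}

#' @export
print.edds_profile <- function(x, ...) {
  tab <- table(factor(x$category_of, levels = c(x$labels, "shared")))
  cat("<edds_profile>", length(x$category_of), "taxa:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an eDDS profile
#'
#' Serialised as a two-column CSV (`taxon,category`) plus an optional JSON
#' provenance block recording the per-survey dominant sets.
#'
#' @param profile An `edds_profile`.
#' @param path CSV path.
#' @param provenance_path Optional JSON path for the provenance block.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, provenance_path = NULL) {
  stopifnot(inherits(profile, "edds_profile"))
  df <- tibble::tibble(taxon = names(profile$category_of),
                       category = unname(profile$category_of))
  df <- dplyr::arrange(df, .data$taxon)
  readr::write_csv(df, path, progress = FALSE)
  if (!is.null(provenance_path)) {
    jsonlite::write_json(list(labels = profile$labels,
                              dominant_sets = profile$provenance),
                         provenance_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_profile
#' @return For `read_profile`, the reconstructed `edds_profile` (provenance
#'   restored when the JSON block is given).
#' @export
read_profile <- function(path, provenance_path = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  category <- setNames(as.character(df$category), as.character(df$taxon))
  if (!is.null(provenance_path)) {
    prov <- jsonlite::read_json(provenance_path, simplifyVector = TRUE)
    labels <- prov$labels
    provenance <- lapply(prov$dominant_sets, as.character)
  } else {
    labels <- setdiff(unique(unname(category)), "shared")
    provenance <- lapply(setNames(labels, labels), function(l) {
      sort(names(category)[category %in% c(l, "shared")])
    })
  }
  structure(list(category_of = category, labels = labels,
                 provenance = provenance),
            class = "edds_profile")
}

#' Leave-one-out stability of a dominant set
#'
#' Omits one observation (water sample or seine day) at a time, recomputes
#' the dominant set on the truncated survey, and compares it with the
#' full-data set. Reports the fraction of iterations with an identical set
#' and, for each differing iteration, which taxa entered and left. In field
#' data the exceptions typically differ only at the last (10th) rank.
#'
#' @param table A `survey_table` with at least two observations.
#' @param heuristic,config Passed to [select_dominants()].
#' @param agg Passed to [rank_abundance()].
#' @return List with `fraction_identical`, `full_set`, and `report` (tibble
#'   with `observation_id`, `identical`, `added`, `dropped`; the last two
#'   comma-separated).
#' @export
loo_profile_stability <- function(table, heuristic = NULL,
                                  config = protocol_config(),
                                  agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  validate_survey_table(table)
  obs <- unique(table$observation_id)
  if (length(obs) < 2) {
    abort("leave-one-out needs at least two observations",
          class = "edds_config_error")
  }
  full_set <- select_dominants(rank_abundance(table, agg = agg),
                               heuristic = heuristic, config = config)
  rows <- lapply(obs, function(o) {
    sub <- table[table$observation_id != o, , drop = FALSE]
    sub <- survey_table(tibble::as_tibble(sub), unit = st_unit(table),
                        survey_label = st_label(table))
    set_o <- withCallingHandlers(
      select_dominants(rank_abundance(sub, agg = agg),
                       heuristic = heuristic, config = config),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble::tibble(
      observation_id = o,
      identical = setequal(set_o, full_set),
      added = paste(sort(setdiff(set_o, full_set)), collapse = ","),
      dropped = paste(sort(setdiff(full_set, set_o)), collapse = ",")
    )
  })
  report <- dplyr::bind_rows(rows)
  list(fraction_identical = mean(report$identical),
       full_set = full_set,
       report = report)
}
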