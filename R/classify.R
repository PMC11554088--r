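#' Category proportions of one observation under a profile
#'
#' Sums an observation's abundance within each profile category (every
#' habitat/season label plus `"shared"`), divides by the observation total,
#' and reports the remainder as `"non_edds"` — the gap at the top of a
#' stacked-proportion column. Proportions are invariant to rescaling the
#' observation, so any abundance unit (copies/L, reads, catch weight,
#' individuals) can be held against a profile built from eDNA copies.
#'
#' @param values Named numeric vector: taxon -> abundance, total > 0.
#' @param profile An [build_profile()] result.
#' @return Named numeric over `c(profile$labels, "shared", "non_edds")`,
#'   summing to 1.
#' @export
category_proportions <- function(values, profile) {
  stopifnot(inherits(profile, "edds_profile"))
  if (is.null(names(values)) || any(is.na(values)) || any(values < 0)) {
    abort("values must be a named non-negative vector",
          class = "edds_schema_error")
  }
  total <- sum(values)
  if (total <= 0) {
    abort("observation total must be positive", class = "edds_empty_error")
  }
  cats <- c(profile$labels, "shared")
  props <- vapply(cats, function(cat) {
    in_cat <- names(values) %in%
      names(profile$category_of)[profile$category_of == cat]
    sum(values[in_cat]) / total
  }, numeric(1))
  c(props, non_edds = 1 - sum(props))
}

#' Evaluate the dominance and classification criteria
#'
#' Two provisional criteria compare an observation with the habitat (or
#' season) it came from. Dominance: do same-category plus shared taxa
#' strictly exceed the dominance threshold (default 80%) of the
#' observation's total? Classification: is the same-category proportion
#' strictly greater than the other-category proportion — with "other"
#' taken as the pooled sum over all other labels (`"pooled_others"`, the
#' default) or as the largest single other label (`"max_other"`)?
#' Observations sitting exactly on a boundary fail (strict inequalities).
#' The predicted label is the argmax over habitat/season-associated labels,
#' ignoring `own_label`; ties (including the all-shared case, where every
#' associated proportion is zero) yield `NA`.
#'
#' @param props Output of [category_proportions()].
#' @param own_label The label of the survey the observation belongs to;
#'   must be one of the profile labels present in `props`.
#' @param config A [protocol_config()].
#' @return One-row tibble of class `criteria_result` with columns
#'   `observation_id` (`NA` here; filled by [classify_survey()]),
#'   `prop_same`, `prop_shared`, `prop_other_total`, `prop_non_edds`,
#'   `dominance`, `classified`, `predicted_label`, plus one `prop_<label>`
#'   column per profile label.
#' @export
evaluate_criteria <- function(props, own_label, config = protocol_config()) {
  labels <- setdiff(names(props), c("shared", "non_edds"))
  if (!(own_label %in% labels)) {
    abort(paste0("unknown own_label: ", own_label), class = "edds_config_error")
  }
  others <- setdiff(labels, own_label)
  prop_same <- unname(props[own_label])
  prop_shared <- unname(props["shared"])
  prop_other_total <- sum(props[others])
  dominance <- (prop_same + prop_shared) > config$dominance_threshold
  classified <- if (config$classification_mode == "pooled_others") {
    prop_same > prop_other_total
  } else {
    prop_same > max(c(props[others], 0))
  }
  assoc <- props[labels]
  top <- labels[assoc == max(assoc)]
  predicted_label <- if (length(top) == 1L) top else NA_character_
  out <- tibble::tibble(
    observation_id = NA_character_,
    prop_same = prop_same,
    prop_shared = prop_shared,
    prop_other_total = prop_other_total,
    prop_non_edds = unname(props["non_edds"]),
    dominance = dominance,
    classified = classified,
    predicted_label = predicted_label
  )
  for (l in labels) out[[paste0("prop_", l)]] <- unname(props[l])
  structure(out, class = c("criteria_result", class(tibble::tibble())))
}

#' Classify every observation of a survey against a profile
#'
#' Applies [category_proportions()] and [evaluate_criteria()] to each
#' observation and to the pooled survey (taxon abundances aggregated over
#' all observations — pooling is abundance-weighted, not a majority vote),
#' then summarises the fraction of observations meeting each criterion.
#' Zero-total observations are flagged unclassifiable, excluded from the
#' summary denominators, and reported with a warning.
#'
#' @param table A `survey_table`; its unit may differ from the unit the
#'   profile was built from.
#' @param profile An `edds_profile`.
#' @param own_label The survey's own category label.
#' @param config A [protocol_config()].
#' @return List with `per_observation` (a `criteria_result` tibble),
#'   `pooled` (one-row `criteria_result`), and `summary` (list: `n`,
#'   `n_dominant`, `n_classified`, `dominance_frac`, `classified_frac`,
#'   `dominance_pct`, `classified_pct` — the percents rounded to whole
#'   numbers as conventionally reported, the fractions exact).
#' @export
classify_survey <- function(table, profile, own_label,
                            config = protocol_config()) {
  validate_survey_table(table)
  stopifnot(inherits(profile, "edds_profile"))
  if (nrow(table) == 0) {
    abort("empty survey table", class = "edds_empty_error")
  }
  m <- st_as_matrix(table)
  totals <- rowSums(m)
  skipped <- rownames(m)[totals <= 0]
  if (length(skipped) > 0) {
    warn(paste0("zero-total observation(s) excluded as unclassifiable: ",
                paste(skipped, collapse = ", ")))
  }
  keep <- rownames(m)[totals > 0]
  if (length(keep) == 0) {
    abort("no observation with positive total", class = "edds_empty_error")
  }
  rows <- lapply(keep, function(o) {
    vals <- setNames(m[o, ], colnames(m))
    res <- evaluate_criteria(category_proportions(vals, profile),
                             own_label, config)
    res$observation_id <- o
    res
  })
  per_obs <- dplyr::bind_rows(rows)
  class(per_obs) <- c("criteria_result", class(tibble::tibble()))

  pooled_values <- colSums(m[keep, , drop = FALSE])
  pooled <- evaluate_criteria(category_proportions(pooled_values, profile),
                              own_label, config)
  pooled$observation_id <- "pooled"

  n <- nrow(per_obs)
  summary <- list(
    n = n,
    n_dominant = sum(per_obs$dominance),
    n_classified = sum(per_obs$classified),
    dominance_frac = mean(per_obs$dominance),
    classified_frac = mean(per_obs$classified),
    dominance_pct = round(100 * mean(per_obs$dominance)),
    classified_pct = round(100 * mean(per_obs$classified)),
    n_excluded = length(skipped)
  )
  list(per_observation = per_obs, pooled = pooled, summary = summary)
}

#' Pooled category shares over a multi-year series
#'
#' Applies a frozen profile to each year's survey in pooled form and
#' returns the per-year category shares, ordered by year — the view used to
#' inspect long-term trends such as a declining habitat-associated share in
#' historical seine records.
#'
#' @param tables Named list, year -> `survey_table` (names sortable as
#'   years); each non-empty.
#' @param profile An `edds_profile`.
#' @return Tibble with columns `year`, `category`, `share`, years in
#'   ascending order, categories in profile order then `"shared"`,
#'   `"non_edds"`.
#' @export
timeseries_category_shares <- function(tables, profile) {
  stopifnot(inherits(profile, "edds_profile"))
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("tables must be a named (year) list", class = "edds_schema_error")
  }
  years <- names(tables)[order(names(tables))]
  rows <- lapply(years, function(y) {
    tb <- tables[[y]]
    validate_survey_table(tb)
    m <- st_as_matrix(tb)
    props <- category_proportions(colSums(m), profile)
    tibble::tibble(year = y, category = names(props),
                   share = unname(props))
  })
  dplyr::bind_rows(rows)
}
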