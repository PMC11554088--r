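#' Protocol configuration
#'
#' Bundles the handful of thresholds the eDDS protocol depends on. Defaults
#' follow the protocol as published: the ten most abundant taxa define the
#' dominant set, dominance requires own-category plus shared taxa to exceed
#' 80% of an observation's total, tag-jump detections below 0.1% of a
#' taxon's run total are zeroed, and binomial intervals are reported at 95%.
#'
#' @param top_n Number of top-ranked taxa forming the dominant set (default
#'   10).
#' @param dominance_threshold Strict lower bound on own + shared proportion
#'   for the dominance criterion (default 0.80).
#' @param tagjump_threshold Per-taxon detection filter: cells below this
#'   fraction of the taxon's run total are zeroed (default 0.001).
#' @param ci_level Confidence level for binomial intervals (default 0.95).
#' @param spike_copies Copy number of the internal standard added per
#'   reaction; all proportional results are invariant to its value.
#' @param dominance_heuristic How dominants are selected: `"top_n"` (the
#'   default protocol), `"cumulative_share"` (shortest prefix exceeding
#'   `cumulative_threshold` of total abundance), or `"min_share"` (all taxa
#'   whose share exceeds `min_share_threshold`).
#' @param cumulative_threshold Cumulative-share cut for the
#'   `"cumulative_share"` heuristic (default 0.90, strict).
#' @param min_share_threshold Per-taxon share cut for the `"min_share"`
#'   heuristic (default 0.01, strict).
#' @param classification_mode `"pooled_others"` compares the own-category
#'   proportion against the sum over all other habitat/season categories;
#'   `"max_other"` compares against the largest single other category.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(top_n = 10L,
                            dominance_threshold = 0.80,
                            tagjump_threshold = 0.001,
                            ci_level = 0.95,
                            spike_copies = 1000,
                            dominance_heuristic = c("top_n", "cumulative_share",
                                                    "min_share"),
                            cumulative_threshold = 0.90,
                            min_share_threshold = 0.01,
                            classification_mode = c("pooled_others",
                                                    "max_other")) {
  dominance_heuristic <- match.arg(dominance_heuristic)
  classification_mode <- match.arg(classification_mode)
  top_n <- as.integer(top_n)
  stopifnot(top_n >= 1L, spike_copies > 0)
  for (f in c(dominance_threshold, tagjump_threshold, ci_level,
              cumulative_threshold, min_share_threshold)) {
    if (!(is.numeric(f) && f > 0 && f < 1)) {
      abort("all protocol fractions must lie strictly in (0, 1)",
            class = "edds_config_error")
    }
  }
  structure(list(top_n = top_n,
                 dominance_threshold = dominance_threshold,
                 tagjump_threshold = tagjump_threshold,
                 ci_level = ci_level,
                 spike_copies = spike_copies,
                 dominance_heuristic = dominance_heuristic,
                 cumulative_threshold = cumulative_threshold,
                 min_share_threshold = min_share_threshold,
                 classification_mode = classification_mode),
            class = "protocol_config")
}

#' Read a protocol configuration from a YAML file
#'
#' Keys mirror the arguments of [protocol_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(protocol_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown protocol_config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "edds_config_error")
  }
  do.call(protocol_config, vals)
}

#' Taxon lumping and exclusion maps
#'
#' The 12S amplicon does not distinguish some regional species, so catch
#' records are lumped to match the eDNA identifications (e.g. the two
#' *Menticirrhus* species to "Menticirrhus spp."). Cartilaginous and
#' freshwater taxa are excluded before any proportion is computed, so "bony
#' fish" denominators contain only retained taxa. Both maps are supplied by
#' the user; no taxonomy is inferred.
#'
#' @param lump_map Named character vector: names are source taxa, values the
#'   lumped label. Must be idempotent: a lump target may not itself be
#'   mapped elsewhere.
#' @param exclusion_set Character vector of taxa to drop.
#' @param standard_taxon Name of the internal spike-in standard (default
#'   `"Struthio camelus"`, the ostrich 12S amplicon). May appear in neither
#'   map.
#' @return A list of class `taxon_maps`.
#' @export
taxon_maps <- function(lump_map = character(),
                       exclusion_set = character(),
                       standard_taxon = "Struthio camelus") {
  lump_map <- vapply(lump_map, as.character, character(1))
  exclusion_set <- as.character(exclusion_set)
  moved_targets <- intersect(unname(lump_map), names(lump_map))
  moved_targets <- moved_targets[lump_map[moved_targets] != moved_targets]
  if (length(moved_targets) > 0) {
    abort(paste0("lump_map is not idempotent; target(s) also remapped: ",
                 paste(moved_targets, collapse = ", ")),
          class = "edds_config_error")
  }
  if (any(unname(lump_map) %in% exclusion_set)) {
    abort("a lump target is in the exclusion set; exclude the sources instead",
          class = "edds_config_error")
  }
  if (standard_taxon %in% c(names(lump_map), exclusion_set)) {
    abort("standard_taxon may not be lumped or excluded",
          class = "edds_config_error")
  }
  structure(list(lump_map = lump_map,
                 exclusion_set = exclusion_set,
                 standard_taxon = standard_taxon),
            class = "taxon_maps")
}

#' Read taxon maps from CSV files
#'
#' @param lump_path Two-column CSV (`from,to`) or `NULL` for no lumping.
#' @param exclusion_path One-column CSV (`taxon`) or `NULL` for no
#'   exclusions.
#' @param standard_taxon Spike-in standard name.
#' @return A `taxon_maps`.
#' @export
read_taxon_maps <- function(lump_path = NULL, exclusion_path = NULL,
                            standard_taxon = "Struthio camelus") {
  lump <- character()
  if (!is.null(lump_path)) {
    df <- readr::read_csv(lump_path, show_col_types = FALSE, progress = FALSE)
    lump <- setNames(as.character(df[[2]]), as.character(df[[1]]))
  }
  excl <- character()
  if (!is.null(exclusion_path)) {
    df <- readr::read_csv(exclusion_path, show_col_types = FALSE,
                          progress = FALSE)
    excl <- as.character(df[[1]])
  }
  taxon_maps(lump, excl, standard_taxon)
}
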