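# Small deterministic fixtures shared across test files.

# a random long-format survey table with n_obs observations over a taxon pool
random_survey_table <- function(n_obs = 5, n_taxa = 10, unit = "reads",
                                survey_label = "fixture", seed = 1,
                                with_meta = FALSE) {
  set.seed(seed)
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  obs <- sprintf("obs_%02d", seq_len(n_obs))
  df <- expand.grid(observation_id = obs, taxon = taxa,
                    stringsAsFactors = FALSE)
  df$value <- rpois(nrow(df), 20)
  df <- df[df$value > 0, ]
  if (with_meta) {
    df$date <- "2022-06-01"
    df$group_key <- paste0("day_", match(df$observation_id, obs) %% 3 + 1)
    df$volume_liters <- round(runif(nrow(df), 0.3, 1.0), 3)[
      match(df$observation_id, df$observation_id)]
    # one volume per observation
    vols <- stats::setNames(round(runif(n_obs, 0.3, 1), 3), obs)
    df$volume_liters <- vols[df$observation_id]
  }
  survey_table(df, unit = unit, survey_label = survey_label)
}

# the canonical three-survey toy profile: a,b sandy-only; c rocky-only;
# d estuary-only; s shared by all
toy_profile <- function() {
  build_profile(list(sandy = c("a", "b", "s"),
                     rocky = c("c", "s"),
                     estuary = c("d", "s")))
}

# a tiny study config that keeps simulation-heavy tests fast; named
# arguments in ... override the small defaults
small_config <- function(seed, ...) {
  args <- list(n_habitats = 2, habitat_labels = c("A", "B"),
               species_per_habitat_pool = 20, n_planted_own = 4,
               n_planted_shared = 2, n_samples = 6,
               read_depth_mean = 5000, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
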