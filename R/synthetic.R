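#' Synthetic study configuration
#'
#' Parameters of the synthetic survey generator. The defaults describe a
#' three-habitat coastal study shaped like the field design the protocol
#' was developed on: each habitat community holds 50 species whose mean
#' relative abundances follow a log-normal SAD (sigma = 3 calibrated so the
#' ten commonest taxa typically hold 92-97% of abundance, the hollow-curve
#' strength seen in coastal fish surveys); 6 habitat-specific and
#' 4 shared dominants are planted into the top ranks of every habitat; each
#' survey collects 18 one-liter-scale water samples sequenced to a negative
#' -binomial depth around 50,000 reads with Dirichlet compositional noise;
#' every library carries a constant-copy spike-in standard at roughly 10%
#' of reads; and 0.2% of reads jump to a random other library in the run.
#'
#' @param n_habitats Number of habitat surveys (default 3).
#' @param habitat_labels Labels; defaults to sandy/rocky/estuary for 3.
#' @param species_per_habitat_pool Species per habitat community, planted
#'   dominants included (default 50, making the top ten 20% of taxa).
#' @param lognormal_mu,lognormal_sigma Log-normal SAD of mean relative
#'   abundances (defaults 0 and 3).
#' @param n_planted_own Habitat-specific dominants planted per habitat
#'   (default 6). Own sets are disjoint across habitats by construction.
#' @param n_planted_shared Dominants shared by all habitats (default 4).
#' @param n_samples Water samples per survey (default 18).
#' @param read_depth_mean,read_depth_dispersion Negative-binomial library
#'   depth (mu, size); defaults 50000 and 10.
#' @param dirichlet_concentration Per-sample compositional noise: sample
#'   compositions are Dirichlet with this total concentration around the
#'   community (default 100; smaller = noisier samples).
#' @param spike_copies Copy number of the internal standard (default 1000).
#' @param spike_read_fraction Standard reads as a fraction of library depth
#'   (default 0.1).
#' @param volume_range Uniform range of filtered liters per sample
#'   (default 0.25-0.95 L, the span seen when filters clog).
#' @param tagjump_rate Probability that a read migrates to a random other
#'   library in the run (default 0.002).
#' @param catch_noise_sigma Log-normal sigma of per-taxon catchability in
#'   gear surveys (default 0.5).
#' @param catch_mean_individuals Expected individuals (or kg) per haul
#'   (default 500).
#' @param seasons Labels for the seasonal design (default winter/summer).
#' @param turnover_fraction Fraction of each season's planted dominants
#'   that are season-specific rather than shared (default 0.9; 1 means
#'   complete turnover, no shared taxa).
#' @param seed Integer seed; mandatory — all generator randomness flows
#'   from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_habitats = 3L,
                             habitat_labels = NULL,
                             species_per_habitat_pool = 50L,
                             lognormal_mu = 0,
                             lognormal_sigma = 3,
                             n_planted_own = 6L,
                             n_planted_shared = 4L,
                             n_samples = 18L,
                             read_depth_mean = 50000,
                             read_depth_dispersion = 10,
                             dirichlet_concentration = 100,
                             spike_copies = 1000,
                             spike_read_fraction = 0.1,
                             volume_range = c(0.25, 0.95),
                             tagjump_rate = 0.002,
                             catch_noise_sigma = 0.5,
                             catch_mean_individuals = 500,
                             seasons = c("winter", "summer"),
                             turnover_fraction = 0.9,
                             seed) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("a numeric seed is mandatory", class = "edds_config_error")
  }
  if (is.null(habitat_labels)) {
    habitat_labels <- if (n_habitats == 3L) c("sandy", "rocky", "estuary")
                      else paste0("habitat_", seq_len(n_habitats))
  }
  stopifnot(length(habitat_labels) == n_habitats,
            !anyDuplicated(habitat_labels))
  if (n_planted_own + n_planted_shared > species_per_habitat_pool) {
    abort("planted dominants exceed the species pool",
          class = "edds_config_error")
  }
  for (r in c(tagjump_rate, spike_read_fraction, turnover_fraction)) {
    if (!(r >= 0 && r <= 1)) {
      abort("rates must lie in [0, 1]", class = "edds_config_error")
    }
  }
  stopifnot(lognormal_sigma >= 0, dirichlet_concentration > 0,
            read_depth_mean > 0, read_depth_dispersion > 0,
            n_samples >= 1, volume_range[1] > 0,
            volume_range[2] >= volume_range[1])
  structure(list(n_habitats = as.integer(n_habitats),
                 habitat_labels = habitat_labels,
                 species_per_habitat_pool = as.integer(species_per_habitat_pool),
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 n_planted_own = as.integer(n_planted_own),
                 n_planted_shared = as.integer(n_planted_shared),
                 n_samples = as.integer(n_samples),
                 read_depth_mean = read_depth_mean,
                 read_depth_dispersion = read_depth_dispersion,
                 dirichlet_concentration = dirichlet_concentration,
                 spike_copies = spike_copies,
                 spike_read_fraction = spike_read_fraction,
                 volume_range = volume_range,
                 tagjump_rate = tagjump_rate,
                 catch_noise_sigma = catch_noise_sigma,
                 catch_mean_individuals = catch_mean_individuals,
                 seasons = seasons,
                 turnover_fraction = turnover_fraction,
                 seed = as.integer(seed),
                 standard_taxon = "Struthio camelus"),
            class = "synthetic_config")
}

#' Generate seasonal communities
#'
#' Seasonal analog of [generate_communities()]: the same number of planted
#' dominants per season (`n_planted_own + n_planted_shared`), split so that
#' a fraction `turnover_fraction` of them are season-specific and the rest
#' shared between seasons. `turnover_fraction = 1` gives complete turnover
#' (no shared taxa), mirroring the near-complete winter-summer turnover
#' seen in coastal trawl surveys.
#'
#' @inheritParams generate_communities
#' @return As [generate_communities()], with season labels.
#' @export
generate_seasonal_communities <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n_total <- config$n_planted_own + config$n_planted_shared
  n_shared <- round((1 - config$turnover_fraction) * n_total)
  generate_communities(config, labels = config$seasons,
                       n_own = n_total - n_shared, n_shared = n_shared,
                       seed = seed)
}

# one Dirichlet draw; zero-concentration components stay exactly zero
.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate habitat communities with planted dominants
#'
#' Draws each habitat's species abundance distribution from a log-normal,
#' then forces the planted taxa (habitat-specific "own" dominants plus the
#' shared set) into the top ranks: the largest draws are assigned, in
#' random order, to the planted taxa, and the remaining draws to
#' habitat-specific tail taxa. Relative abundances are normalised to 1.
#' The planted truth is returned alongside so recovery can be scored
#' unambiguously.
#'
#' @param config A [synthetic_config()].
#' @param labels Survey labels (default the config's habitat labels; pass
#'   season labels for the seasonal design).
#' @param n_own,n_shared Planted counts (default from config).
#' @param seed Seed; default `config$seed`. Pass `NULL` to continue the
#'   current RNG stream (used internally by [simulate_study()]).
#' @return List: `communities` (label -> named numeric, sums to 1),
#'   `truth` (list: `categories` named vector over planted taxa,
#'   `own` per-label sets, `shared`).
#' @export
generate_communities <- function(config, labels = config$habitat_labels,
                                 n_own = config$n_planted_own,
                                 n_shared = config$n_planted_shared,
                                 seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  pool <- config$species_per_habitat_pool
  if (n_own + n_shared > pool) {
    abort("planted dominants exceed the species pool",
          class = "edds_config_error")
  }
  shared_taxa <- if (n_shared > 0) sprintf("shared_dom_%02d", seq_len(n_shared))
                 else character()
  communities <- list()
  own_sets <- list()
  for (lab in labels) {
    own_taxa <- if (n_own > 0) sprintf("%s_dom_%02d", lab, seq_len(n_own))
                else character()
    n_tail <- pool - n_own - n_shared
    tail_taxa <- if (n_tail > 0) sprintf("%s_tail_%02d", lab, seq_len(n_tail))
                 else character()
    draws <- sort(rlnorm(pool, config$lognormal_mu, config$lognormal_sigma),
                  decreasing = TRUE)
    planted <- sample(c(own_taxa, shared_taxa))
    taxa <- c(planted, tail_taxa)
    ab <- setNames(draws / sum(draws), taxa)
    communities[[lab]] <- ab[order(names(ab))]
    own_sets[[lab]] <- own_taxa
  }
  categories <- c(
    setNames(rep(labels, each = n_own), unlist(own_sets)),
    setNames(rep("shared", n_shared), shared_taxa)
  )
  list(communities = communities,
       truth = list(categories = categories, own = own_sets,
                    shared = shared_taxa))
}

#' Move reads between libraries to mimic tag jumping
#'
#' Each read independently migrates to a uniformly random *other* library
#' of the run with probability `rate`. Reads are moved, never duplicated,
#' so per-taxon run totals are conserved.
#'
#' @param reads Libraries x taxa count matrix.
#' @param rate Migration probability per read.
#' @return Contaminated matrix, same shape and column sums.
#' @export
inject_tag_jumps <- function(reads, rate) {
  validate_read_matrix(reads)
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || nrow(reads) < 2) return(reads)
  L <- nrow(reads)
  out <- reads
  for (t in seq_len(ncol(reads))) {
    jumped <- rbinom(L, reads[, t], rate)
    if (sum(jumped) == 0) next
    out[, t] <- out[, t] - jumped
    for (i in which(jumped > 0)) {
      dest <- rmultinom(1, jumped[i], rep(1 / (L - 1), L - 1))[, 1]
      out[-i, t] <- out[-i, t] + dest
    }
  }
  out
}

#' Simulate one eDNA metabarcoding survey
#'
#' Per sample: library depth is negative-binomial (zero depths redrawn, up
#' to 10 tries); the sample composition is Dirichlet around the community
#' with the configured concentration; fish reads are multinomial at that
#' depth; spike-in standard reads are added at `spike_read_fraction` of
#' depth; the filtered volume is uniform on `volume_range`. Tag-jump
#' migration is applied within the survey's libraries unless the caller
#' assembles several surveys into one multiplexed run first (see
#' [simulate_study()]).
#'
#' @param community Named numeric relative abundances (sums to 1).
#' @param config A [synthetic_config()].
#' @param label Library name prefix.
#' @param tagjump Apply [inject_tag_jumps()] within this survey? Default
#'   `TRUE`.
#' @param seed Seed; default `config$seed`, `NULL` to continue the stream.
#' @return List: `reads` (libraries x taxa incl. the standard column),
#'   `volumes` (named liters).
#' @export
simulate_edna_survey <- function(community, config, label = "survey",
                                 tagjump = TRUE, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(community) - 1) > 1e-8) {
    abort("community must be normalised", class = "edds_config_error")
  }
  n <- config$n_samples
  taxa <- names(community)
  reads <- matrix(0, nrow = n, ncol = length(taxa) + 1,
                  dimnames = list(sprintf("%s_s%02d", label, seq_len(n)),
                                  c(taxa, config$standard_taxon)))
  for (i in seq_len(n)) {
    depth <- 0; tries <- 0
    while (depth == 0 && tries < 10) {
      depth <- rnbinom(1, size = config$read_depth_dispersion,
                       mu = config$read_depth_mean)
      tries <- tries + 1
    }
    if (depth == 0) {
      inform(sprintf("library %s drew depth 0 ten times; left empty",
                     rownames(reads)[i]))
    }
    comp <- .rdirichlet1(config$dirichlet_concentration * community)
    fish <- if (depth > 0) rmultinom(1, depth, comp)[, 1] else rep(0, length(taxa))
    reads[i, taxa] <- fish
    reads[i, config$standard_taxon] <- round(config$spike_read_fraction * depth)
  }
  if (tagjump) reads <- inject_tag_jumps(reads, config$tagjump_rate)
  volumes <- setNames(runif(n, config$volume_range[1], config$volume_range[2]),
                      rownames(reads))
  list(reads = reads, volumes = volumes)
}

#' Simulate a gear-based catch survey
#'
#' Expected catch per haul is proportional to community abundance times a
#' per-taxon log-normal catchability drawn once per survey; realised
#' catches are Poisson counts (`"individuals"`) or gamma weights
#' (`"catch_weight_kg"`, shape 2).
#'
#' @param community Named numeric relative abundances.
#' @param config A [synthetic_config()].
#' @param n_hauls Hauls/trawls (default 30).
#' @param unit `"individuals"` or `"catch_weight_kg"`.
#' @param label Survey label.
#' @param seed Seed; default `config$seed`, `NULL` to continue the stream.
#' @return A `survey_table` in the requested unit.
#' @export
simulate_catch_survey <- function(community, config, n_hauls = 30,
                                  unit = c("individuals", "catch_weight_kg"),
                                  label = "catch", seed = config$seed) {
  unit <- match.arg(unit)
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  q <- rlnorm(length(community), 0, config$catch_noise_sigma)
  w <- community * q
  expected <- config$catch_mean_individuals * w / sum(w)
  m <- matrix(0, nrow = n_hauls, ncol = length(community),
              dimnames = list(sprintf("%s_h%02d", label, seq_len(n_hauls)),
                              names(community)))
  for (h in seq_len(n_hauls)) {
    m[h, ] <- if (unit == "individuals") {
      rpois(length(expected), expected)
    } else {
      ifelse(expected > 0, rgamma(length(expected), shape = 2,
                                  scale = expected / 2), 0)
    }
  }
  st_from_matrix(m, unit = unit, survey_label = label)
}

#' Simulate a full multi-habitat study as one sequencing run
#'
#' Generates the habitat communities, simulates every habitat's eDNA
#' survey, multiplexes all libraries into one run (the taxon universe is
#' the union across habitats), applies tag-jump migration across the whole
#' run, and simulates a concurrent catch survey per habitat. This is the
#' configuration under which habitat-specific taxa are truly absent from
#' other habitats' libraries, so cross-library contamination and its
#' filtering can be studied end to end.
#'
#' @param config A [synthetic_config()].
#' @return List: `run_reads` (all libraries x union taxa + standard, after
#'   tag jumping), `surveys` (per habitat: `reads` slice, `volumes`),
#'   `catches` (per habitat `survey_table` of individuals), `communities`,
#'   `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  gen <- generate_communities(config, seed = NULL)
  surveys <- list()
  for (lab in config$habitat_labels) {
    surveys[[lab]] <- simulate_edna_survey(gen$communities[[lab]], config,
                                           label = lab, tagjump = FALSE,
                                           seed = NULL)
  }
  taxa <- sort(unique(unlist(lapply(surveys, function(s) colnames(s$reads)))))
  taxa <- c(setdiff(taxa, config$standard_taxon), config$standard_taxon)
  run <- do.call(rbind, lapply(surveys, function(s) {
    m <- matrix(0, nrow = nrow(s$reads), ncol = length(taxa),
                dimnames = list(rownames(s$reads), taxa))
    m[, colnames(s$reads)] <- s$reads
    m
  }))
  run <- inject_tag_jumps(run, config$tagjump_rate)
  for (lab in config$habitat_labels) {
    surveys[[lab]]$reads <- run[rownames(surveys[[lab]]$reads), , drop = FALSE]
  }
  catches <- list()
  for (lab in config$habitat_labels) {
    catches[[lab]] <- simulate_catch_survey(gen$communities[[lab]], config,
                                            unit = "individuals",
                                            label = lab, seed = NULL)
  }
  list(run_reads = run, surveys = surveys, catches = catches,
       communities = gen$communities, truth = gen$truth)
}

#' Run the whole pipeline on a simulated study and score recovery
#'
#' The acceptance harness: simulates a study, filters tag jumps across the
#' run, converts reads to copies/L per habitat, builds the eDDS habitat
#' profile from the top-ranked taxa, and scores (i) exact recovery of the
#' planted profile (same taxa, same own/shared labels), (ii) per-sample
#' dominance and classification pass rates with each habitat as its own
#' label, and (iii) leave-one-out stability of each habitat's dominant
#' set.
#'
#' @param config A [synthetic_config()].
#' @param protocol A [protocol_config()]; `spike_copies` is taken from
#'   `config`.
#' @return List of class `edds_recovery`: `profile_recovered` (logical),
#'   `profile`, `truth_categories`, `dominance_frac`, `classified_frac`,
#'   `n_observations`, `loo_fraction_identical` (named per habitat),
#'   `per_habitat` (summaries from [classify_survey()]).
#' @export
end_to_end_recovery <- function(config, protocol = protocol_config()) {
  study <- simulate_study(config)
  protocol$spike_copies <- config$spike_copies
  filtered <- filter_tag_jumps(study$run_reads,
                               threshold = protocol$tagjump_threshold)
  copies <- list()
  for (lab in config$habitat_labels) {
    sub <- filtered[rownames(study$surveys[[lab]]$reads), , drop = FALSE]
    copies[[lab]] <- reads_to_copies(sub,
                                     standard_taxon = config$standard_taxon,
                                     spike_copies = config$spike_copies,
                                     volumes = study$surveys[[lab]]$volumes,
                                     survey_label = lab)
  }
  dominant_sets <- lapply(copies, function(tb) {
    select_dominants(rank_abundance(tb), config = protocol)
  })
  profile <- build_profile(dominant_sets)
  truth <- study$truth$categories
  recovered <- setequal(names(profile$category_of), names(truth)) &&
    all(profile$category_of[names(truth)] == truth)

  per_habitat <- list()
  dom <- 0; cls <- 0; n_obs <- 0
  loo <- setNames(numeric(length(config$habitat_labels)),
                  config$habitat_labels)
  for (lab in config$habitat_labels) {
    res <- classify_survey(copies[[lab]], profile, own_label = lab,
                           config = protocol)
    per_habitat[[lab]] <- res$summary
    dom <- dom + res$summary$n_dominant
    cls <- cls + res$summary$n_classified
    n_obs <- n_obs + res$summary$n
    loo[lab] <- loo_profile_stability(copies[[lab]],
                                      config = protocol)$fraction_identical
  }
  structure(list(profile_recovered = recovered,
                 profile = profile,
                 truth_categories = truth,
                 dominance_frac = dom / n_obs,
                 classified_frac = cls / n_obs,
                 n_observations = n_obs,
                 loo_fraction_identical = loo,
                 per_habitat = per_habitat),
            class = "edds_recovery")
}

#' @export
print.edds_recovery <- function(x, ...) {
  cat(sprintf(paste0("<edds_recovery> profile recovered: %s; dominance %d%%,",
                     " classification %d%% of %d observations\n"),
              x$profile_recovered, round(100 * x$dominance_frac),
              round(100 * x$classified_frac), x$n_observations))
  invisible(x)
}
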