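test_that("config validation catches impossible designs", {
  expect_error(synthetic_config(), class = "edds_config_error")  # no seed
  expect_error(synthetic_config(species_per_habitat_pool = 8,
                                n_planted_own = 6, n_planted_shared = 4,
                                seed = 1),
               class = "edds_config_error")
  expect_error(synthetic_config(tagjump_rate = 1.5, seed = 1),
               class = "edds_config_error")
})

test_that("planted dominants occupy the true top ranks of every habitat", {
  cfg <- synthetic_config(seed = 101)
  gen <- generate_communities(cfg)
  for (lab in cfg$habitat_labels) {
    com <- sort(gen$communities[[lab]], decreasing = TRUE)
    top10 <- names(com)[1:10]
    own <- gen$truth$own[[lab]]
    expect_setequal(top10, c(own, gen$truth$shared))
    expect_equal(sum(gen$communities[[lab]]), 1, tolerance = 1e-12)
  }
  # own sets pairwise disjoint; shared common to all
  expect_length(Reduce(intersect, gen$truth$own), 0)
  expect_length(gen$truth$shared, cfg$n_planted_shared)
})

test_that("sigma = 0 collapses the tail to equal abundances", {
  cfg <- synthetic_config(lognormal_sigma = 0, seed = 5)
  gen <- generate_communities(cfg)
  com <- gen$communities[[1]]
  tail_vals <- com[grepl("tail", names(com))]
  expect_lt(diff(range(tail_vals)), 1e-12)
})

test_that("read shares converge to community shares without noise sources", {
  cfg <- small_config(seed = 7, dirichlet_concentration = 1e9,
                      tagjump_rate = 0, read_depth_mean = 1e6,
                      read_depth_dispersion = 1e6, n_samples = 2)
  gen <- generate_communities(cfg)
  com <- gen$communities[["A"]]
  sim <- simulate_edna_survey(com, cfg, label = "A", seed = 7)
  fish <- sim$reads[, names(com)]
  shares <- fish[1, ] / sum(fish[1, ])
  expect_lt(max(abs(shares - com)), 0.01)
})

test_that("spike-in reads sit at the configured fraction of depth", {
  cfg <- small_config(seed = 3, spike_read_fraction = 0.1,
                      read_depth_mean = 10000, tagjump_rate = 0)
  gen <- generate_communities(cfg)
  sim <- simulate_edna_survey(gen$communities[["A"]], cfg, label = "A",
                              seed = 3)
  fish_depth <- rowSums(sim$reads[, setdiff(colnames(sim$reads),
                                            cfg$standard_taxon)])
  std <- sim$reads[, cfg$standard_taxon]
  expect_equal(std, round(0.1 * fish_depth), tolerance = 1e-9)
})

test_that("tag jumping moves reads without creating or destroying them", {
  set.seed(99)
  m <- matrix(rpois(80, 500), nrow = 8,
              dimnames = list(sprintf("l%d", 1:8), sprintf("t%d", 1:10)))
  out <- inject_tag_jumps(m, 0.05)
  expect_equal(colSums(out), colSums(m))
  expect_true(any(out != m))
  expect_identical(inject_tag_jumps(m, 0), m)
})

test_that("catch surveys track the community in the noiseless limit", {
  cfg <- small_config(seed = 17, catch_noise_sigma = 0,
                      catch_mean_individuals = 1e5)
  gen <- generate_communities(cfg)
  com <- gen$communities[["A"]]
  ct <- simulate_catch_survey(com, cfg, n_hauls = 20, unit = "individuals",
                              seed = 17)
  expect_equal(st_unit(ct), "individuals")
  expect_true(all(ct$value >= 0 & ct$value == round(ct$value)))
  shares <- rank_abundance(ct)
  expect_lt(max(abs(shares$share - sort(com, decreasing = TRUE)[shares$taxon])),
            0.01)
})

test_that("catch and eDNA abundances stay rank-concordant under noise", {
  # 30 taxa, catchability sigma = 0.5; median Spearman over 100 seeds > 0.7
  rhos <- sapply(1:100, function(s) {
    cfg <- synthetic_config(n_habitats = 2, habitat_labels = c("A", "B"),
                            species_per_habitat_pool = 30, n_planted_own = 6,
                            n_planted_shared = 4, n_samples = 4,
                            read_depth_mean = 20000, catch_noise_sigma = 0.5,
                            seed = s)
    gen <- generate_communities(cfg, seed = s)
    com <- gen$communities[["A"]]
    edna <- simulate_edna_survey(com, cfg, label = "A", seed = s)
    fish <- colSums(edna$reads[, names(com)])
    catch <- simulate_catch_survey(com, cfg, n_hauls = 20, seed = s + 1)
    agg <- rank_abundance(catch)
    y <- stats::setNames(agg$value, agg$taxon)
    abundance_concordance(fish[fish > 0], y)$rho
  })
  expect_gt(median(rhos), 0.7)
})

test_that("identical config and seed give bit-identical studies", {
  cfg <- small_config(seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$run_reads, s2$run_reads)
  expect_identical(s1$surveys[["B"]]$volumes, s2$surveys[["B"]]$volumes)
  expect_identical(tibble::as_tibble(s1$catches[["A"]]),
                   tibble::as_tibble(s2$catches[["A"]]))
})

test_that("an all-shared design is dominant but unclassifiable", {
  # every community taxon is a shared planted dominant: the top-10 of both
  # habitats coincide by construction, so no habitat-associated label exists.
  # sigma = 1 keeps every taxon far above the 0.1% run-total filter cut.
  cfg <- synthetic_config(n_habitats = 2, habitat_labels = c("A", "B"),
                          species_per_habitat_pool = 10, n_planted_own = 0,
                          n_planted_shared = 10, n_samples = 6,
                          lognormal_sigma = 1,
                          read_depth_mean = 20000, seed = 41)
  rec <- suppressWarnings(end_to_end_recovery(cfg))
  expect_gt(rec$dominance_frac, 0.9)
  expect_equal(rec$classified_frac, 0)
})

test_that("complete seasonal turnover leaves no shared taxa", {
  cfg <- synthetic_config(turnover_fraction = 1, seed = 53)
  gen <- generate_seasonal_communities(cfg)
  profile <- build_profile(lapply(gen$communities, function(com) {
    names(sort(com, decreasing = TRUE))[1:10]
  }))
  expect_false(any(profile$category_of == "shared"))
  expect_length(gen$truth$shared, 0)

  # half turnover plants shared seasonal dominants
  gen2 <- generate_seasonal_communities(synthetic_config(
    turnover_fraction = 0.5, seed = 53))
  expect_length(gen2$truth$shared, 5)
})

test_that("more samples never hurt median planted-set recovery", {
  # fixed-seed 3-point grid on a small, well-separated design
  frac_recovered <- function(n_samples) {
    mean(sapply(1:12, function(s) {
      cfg <- synthetic_config(n_habitats = 2, habitat_labels = c("A", "B"),
                              species_per_habitat_pool = 15,
                              n_planted_own = 3, n_planted_shared = 2,
                              lognormal_sigma = 2.5,
                              dirichlet_concentration = 500,
                              n_samples = n_samples,
                              read_depth_mean = 20000,
                              seed = 1000 + s)
      rec <- suppressWarnings(end_to_end_recovery(
        cfg, protocol_config(top_n = 5)))
      rec$profile_recovered
    }))
  }
  grid <- sapply(c(2, 6, 14), frac_recovered)
  expect_true(all(diff(grid) >= -1e-9))
})
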