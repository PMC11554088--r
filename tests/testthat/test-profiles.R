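test_that("rank abundance aggregates, ranks and normalises shares", {
  one <- survey_table(data.frame(observation_id = "o1", taxon = "only",
                                 value = 5), unit = "reads")
  r1 <- rank_abundance(one)
  expect_equal(r1$share, 1)
  expect_equal(r1$cumulative_share, 1)

  two <- survey_table(data.frame(observation_id = c("o1", "o1"),
                                 taxon = c("big", "small"),
                                 value = c(75, 25)), unit = "reads")
  r2 <- rank_abundance(two)
  expect_equal(r2$taxon, c("big", "small"))
  expect_equal(r2$share, c(0.75, 0.25))

  zero <- survey_table(data.frame(observation_id = "o1", taxon = "t",
                                  value = 0), unit = "reads")
  expect_error(rank_abundance(zero), class = "edds_empty_error")
})

test_that("ranking is deterministic: ties break by taxon name ascending", {
  st <- survey_table(data.frame(observation_id = "o1",
                                taxon = c("zeta", "alpha", "mid"),
                                value = c(10, 10, 20)), unit = "reads")
  r <- rank_abundance(st)
  expect_equal(r$taxon, c("mid", "alpha", "zeta"))
})

test_that("shares and cumulative shares satisfy the SAD invariants", {
  set.seed(11)
  for (s in 1:10) {
    st <- random_survey_table(n_obs = 3, n_taxa = 15, seed = s)
    r <- rank_abundance(st)
    expect_equal(sum(r$share), 1, tolerance = 1e-9)
    expect_true(all(diff(r$value) <= 0))
    expect_true(all(diff(r$cumulative_share) >= 0))
    expect_equal(r$cumulative_share[nrow(r)], 1, tolerance = 1e-9)
  }
})

test_that("dominant selection implements all three heuristics", {
  mk <- function(shares) {
    st <- survey_table(data.frame(observation_id = "o",
                                  taxon = sprintf("t%02d", seq_along(shares)),
                                  value = shares), unit = "copies_per_liter")
    rank_abundance(st)
  }
  # fewer taxa than n: everything is dominant
  expect_length(select_dominants(mk(c(5, 4, 3, 2, 1))), 5)

  # cumulative > 0.90 strict: 0.88 after 4 taxa, 0.93 after 5
  r <- mk(c(0.50, 0.20, 0.10, 0.08, 0.05, 0.04, 0.03))
  got <- select_dominants(r, heuristic = "cumulative_share")
  expect_equal(got, sprintf("t%02d", 1:5))

  # min-share > 1% strict
  r2 <- mk(c(0.99, 0.005, 0.005))
  expect_equal(select_dominants(r2, heuristic = "min_share"), "t01")

  # top_n is always a prefix of the ranking
  r3 <- mk(c(9, 8, 7, 6, 5, 4, 3, 2, 1, 1, 1) + 0:10 / 100)
  cfg <- protocol_config(top_n = 4)
  expect_equal(select_dominants(r3, config = cfg), r3$taxon[1:4])
})

test_that("an abundance tie spanning the top-n boundary is flagged", {
  st <- survey_table(data.frame(observation_id = "o",
                                taxon = c("a", "b", "c", "d"),
                                value = c(5, 3, 2, 2)), unit = "reads")
  r <- rank_abundance(st)
  expect_warning(select_dominants(r, config = protocol_config(top_n = 3)),
                 regexp = "tie")
})

test_that("profiles label single-survey taxa by habitat and overlaps shared", {
  p <- toy_profile()
  expect_equal(unname(p$category_of[c("a", "b", "c", "d", "s")]),
               c("sandy", "sandy", "rocky", "estuary", "shared"))

  # identical sets across three surveys: everything shared
  same <- build_profile(list(x = c("u", "v"), y = c("u", "v"),
                             z = c("u", "v")))
  expect_true(all(same$category_of == "shared"))

  # pairwise-disjoint sets: nothing shared
  disj <- build_profile(list(x = "u", y = "v", z = "w"))
  expect_false(any(disj$category_of == "shared"))

  expect_error(build_profile(stats::setNames(list("a", "b"), c("x", "x"))),
               class = "edds_config_error")
  expect_error(build_profile(list(x = "a")), class = "edds_config_error")
})

test_that("profile categories partition the union of dominant sets", {
  set.seed(5)
  pool <- sprintf("sp%02d", 1:15)
  for (i in 1:25) {
    sets <- lapply(1:3, function(j) sample(pool, sample(3:8, 1)))
    names(sets) <- c("A", "B", "C")
    p <- build_profile(sets)
    expect_setequal(names(p$category_of), unique(unlist(sets)))
    # brute-force category per taxon
    for (t in names(p$category_of)) {
      hits <- names(sets)[vapply(sets, function(s) t %in% s, logical(1))]
      expected <- if (length(hits) >= 2) "shared" else hits
      expect_identical(unname(p$category_of[t]), expected)
    }
  }
})

test_that("profiles survive CSV round-trips", {
  p <- toy_profile()
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_profile(p, csv, provenance_path = js)
  back <- read_profile(csv, provenance_path = js)
  expect_equal(back$category_of[sort(names(back$category_of))],
               p$category_of[sort(names(p$category_of))])
  expect_setequal(back$labels, p$labels)
  expect_equal(back$provenance[p$labels], p$provenance[p$labels])
})

test_that("dominant sets and profiles are invariant to rescaling abundances", {
  st <- random_survey_table(n_obs = 4, n_taxa = 20, seed = 21,
                            unit = "copies_per_liter")
  scaled <- survey_table(
    transform(tibble::as_tibble(st), value = value * 137.5),
    unit = "copies_per_liter", survey_label = st_label(st)
  )
  r0 <- rank_abundance(st); r1 <- rank_abundance(scaled)
  expect_equal(r1$share, r0$share, tolerance = 1e-12)
  expect_identical(suppressWarnings(select_dominants(r1)),
                   suppressWarnings(select_dominants(r0)))
})

test_that("leave-one-out stability localises a single-sample rank-10 taxon", {
  # 12 taxa over 4 samples; 'fragile' enters rank 10 only through obs_04
  base <- expand.grid(observation_id = sprintf("obs_%02d", 1:4),
                      taxon = sprintf("common_%02d", 1:9),
                      stringsAsFactors = FALSE)
  base$value <- rep(c(100, 90, 80, 70, 60, 50, 40, 30, 20), each = 4)
  extra <- data.frame(
    observation_id = c("obs_04", rep("obs_01", 2)),
    taxon = c("fragile", "rare_a", "rare_b"),
    value = c(15, 4, 3)
  )
  st <- survey_table(rbind(base, extra), unit = "copies_per_liter")
  loo <- loo_profile_stability(st, config = protocol_config(top_n = 10))
  rep4 <- loo$report[loo$report$observation_id == "obs_04", ]
  expect_false(rep4$identical)
  expect_equal(rep4$dropped, "fragile")          # the rank-10 taxon
  expect_equal(rep4$added, "rare_a")             # its replacement
  expect_equal(loo$fraction_identical, 3 / 4)
})

test_that("identical sample compositions give perfect LOO stability", {
  df <- expand.grid(observation_id = sprintf("o%d", 1:5),
                    taxon = sprintf("t%02d", 1:12),
                    stringsAsFactors = FALSE)
  df$value <- rep(12:1, each = 5)
  st <- survey_table(df, unit = "reads")
  loo <- loo_profile_stability(st)
  expect_equal(loo$fraction_identical, 1.0)
  expect_error(
    loo_profile_stability(
      survey_table(df[df$observation_id == "o1", ], unit = "reads")),
    class = "edds_config_error"
  )
})
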