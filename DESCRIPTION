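Package: eddsr
Title: Dominant-Species Profiles from eDNA Metabarcoding and Gear-Based Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the eDNA-dominant-species (eDDS) protocol: turning
    per-library 12S metabarcoding read tables into absolute copy estimates via
    an internal spike-in standard, filtering tag-jump (index-hopping)
    cross-contamination, building rank-abundance ("hollow curve") profiles of
    the commonest taxa per habitat or season, classifying individual water
    samples, trawls and seine days against those profiles, and summarising
    agreement with exact contingency tests and modified-Wald binomial
    intervals. Includes a synthetic survey generator (log-normal species
    abundance distributions with planted habitat-associated and shared
    dominants, Dirichlet-multinomial read sampling, spike-in, tag jumping, and
    noisy gear catches) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
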