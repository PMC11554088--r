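---
title: "The eDDS protocol: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The eDDS protocol: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eddsr)
```

## The protocol in brief

Species abundance distributions of coastal fish are strongly hollow-curved:
in 12S metabarcoding surveys of northwest-Atlantic habitats the ten
commonest taxa typically account for over nine-tenths of bony-fish eDNA
while representing only a fifth to a quarter of the species detected. The
eDNA-dominant-species (eDDS) protocol turns this into a classification
tool:

1. For each reference survey, aggregate eDNA copies/L per taxon over the
   whole survey and rank taxa. The ten most abundant are that survey's
   eDDS.
2. Across surveys, label each eDDS *habitat-associated* (top ten in exactly
   one survey) or *shared* (top ten in two or more). The labelled set is
   the **eDDS profile** — a frozen object; applying it never touches the
   reference data again.
3. For any new observation, in any abundance unit (copies/L, reads, catch
   weight, individuals), compute the proportion of total abundance falling
   in each profile category; the remainder is *non-eDDS*. Score two
   criteria, both strict:
   * dominance: `p_own + p_shared > 0.80`;
   * classification: `p_own > p_other` (see "Open choices" for what
     "other" means with three or more categories).

The protocol's central assumption is that relative eDNA abundance tracks
relative organism abundance well enough to preserve the identity of the
commonest species — not that it is unbiased per species. Because every
quantity applied downstream is a proportion, results are invariant to the
spike-in copy number, to filtered volume (for pooled comparisons), and to
per-observation rescaling.

## Preprocessing model

**Tag-jump filter.** Multiplexed runs cross-assign a small fraction of
reads between libraries. For each taxon with run total `T`, any library
count `c < threshold × T` (default `threshold = 0.001`) is set to zero;
`c ≥ threshold × T` is kept — "less than" is read strictly, so an
exactly-boundary count survives. Filtering is a single pass against the
*original* totals: iterating to a fixed point could cascade removals, and
is unnecessary because every surviving cell also satisfies the cut against
the reduced totals (the filter is idempotent). The filter's scope is one
input matrix = one sequencing run; if a study spans runs, filter each run's
matrix separately before merging.

**Spike-in quantification.** Each library receives a known copy number of
an ostrich 12S standard before PCR. Copies per liter are
`reads/standard_reads × spike_copies / liters`. Within a library this is a
single multiplicative factor, so copies are exactly proportional to reads
across taxa; a zero standard count is a hard error naming the library
(quantification is impossible there, not zero).

**Lumping and exclusion.** The 12S amplicon cannot separate some regional
congeners, so catch records are lumped to the eDNA resolution via a
user-supplied map (validated idempotent). Cartilaginous and freshwater
taxa are dropped *before* any proportion is formed, so "bony fish"
denominators contain only retained taxa. No taxonomy is inferred; both
lists are explicit inputs.

**Per-day grouping.** Seine surveys have empty hauls and several water
samples per day, so both tables collapse to one observation per day:
individuals summed then divided by hauls; eDNA pooled volume-weighted
(total raw copies / total liters). The unweighted per-sample mean is
available (`edna_agg = "sample_mean"`) because "normalised per volume
filtered" admits either reading; volume-weighted pooling is the default
since it equals the copies/L one would measure had the day's samples been
filtered together.

## Dominance heuristics

Three definitions of "the common species" are supported, all strict:

| heuristic | rule | default |
|---|---|---|
| `top_n` | first *n* ranked taxa | n = 10 |
| `cumulative_share` | shortest prefix with cumulative share > cut | cut = 0.90 |
| `min_share` | all taxa with individual share > cut | cut = 0.01 |

Rank ties are broken by taxon name ascending so every ranking is
deterministic; a tie that spans the `top_n` boundary is additionally
flagged with a warning because the selected set then depends on the
tie-break.

## Statistics

* **Fisher's exact test** uses the probability-mass two-sided definition —
  the p-value sums the probabilities of all tables with the observed
  margins whose point probability does not exceed the observed one (the
  convention of the commercial package commonly used for such analyses).
  2×2 tables enumerate the hypergeometric range; r×c tables are enumerated
  depth-first under a state budget (default 2×10⁶ tables), beyond which
  the function errors and points to the Monte-Carlo fallback
  (`fisher_exact_mc()`, Patefield sampling, reported with its MC standard
  error). Tables reduced to a single non-zero row or column carry no
  association and return p = 1.
* **Binomial intervals** default to the modified Wald (Agresti–Coull)
  form: centre `(x + z²/2)/(n + z²)`, half-width
  `z √(p̃(1−p̃)/(n+z²))`, clipped to [0, 1], with `z` the exact normal
  quantile. The plain Wald interval is exposed under its own name; for
  small `x` it collapses (at x = 1, n = 49 its upper bound is ≈6%, versus
  ≈12% for the modified form) and should not be used for the
  misclassification rates this protocol produces.
* **Concordance** between abundance measures is Spearman's rank
  correlation over the union of taxa with absences as zeros, requiring at
  least three taxa present in both.

## The synthetic generator

`synthetic_config()` describes a study; `simulate_study()` realises it as
one multiplexed sequencing run. What it emulates, per habitat:

* a log-normal SAD of mean relative abundances (`lognormal_sigma = 3`,
  `species_per_habitat_pool = 50`). Sigma is calibrated so the ten
  commonest taxa typically hold 92–97% of abundance while being 20% of the
  species — the hollow-curve strength observed in coastal fish surveys; at
  sigma 2 the top-ten share has median ≈0.84, visibly too flat;
* planted structure: `n_planted_own = 6` habitat-specific plus
  `n_planted_shared = 4` shared dominants receive the largest draws, in
  random order, so the true top ten of every habitat is known exactly and
  recovery can be scored without ambiguity. Tail taxa are
  habitat-specific;
* per-sample compositional noise: Dirichlet around the community with
  total concentration 100 — replicate water samples from one habitat vary
  noticeably but rarely enough to break dominance, matching the behaviour
  of field replicates;
* sequencing: negative-binomial library depth (mean 50 000, size 10),
  multinomial reads at that depth, spike-in standard reads at 10% of
  depth, filtered volumes uniform on 0.25–0.95 L (the span seen when
  filters clog);
* tag jumping: each read independently migrates to a uniformly random
  other library of the run with probability 0.002 — moves, never copies,
  so run totals are conserved;
* gear surveys: expected catch proportional to community abundance times a
  per-taxon log-normal catchability (sigma 0.5) drawn once per survey;
  Poisson individuals or gamma weights, ~500 per haul.

What it does **not** emulate: eDNA transport and decay, PCR amplification
bias, size/age structure, spatial autocorrelation among stations, or
seasonal succession within a survey. Passing tests therefore show the
pipeline's arithmetic and decision rules are correct under the assumed
observation model, not that field data satisfy that model.

All randomness flows from the mandatory `seed`; identical config and seed
give bit-identical studies and byte-identical CSV exports.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold appears; boundary cases
  (exactly 0.80 dominance, tied predicted labels) fail and, where useful,
  warn. An observation whose associated-category proportions are all zero
  gets no predicted label.
* Zero-total observations are flagged unclassifiable and excluded from
  summary denominators, with a warning — not silently dropped, not an
  error.
* All-zero read matrices pass the tag-jump filter unchanged; an all-zero
  survey cannot be ranked (error).
* Proportions are validated to sum to 1 within 1e-9; CSV round-trips are
  exact to at least 12 decimals; row order in every writer is sorted, so
  outputs are deterministic.
* Summary percentages are reported rounded to whole percent (the
  conventional reporting style) with exact fractions retained alongside.

## Open choices, resolved

* **"Other-habitat" comparison.** With three or more categories,
  "own > other" is ambiguous. Default `pooled_others` treats all other
  associated categories as one aggregate; `max_other` compares against the
  largest single one. Both are exposed; neither is asserted as canonical.
* **Aggregate = sum.** Survey-level ranking aggregates by sum of copies/L
  across observations ("aggregate abundance"); a mean-per-observation
  option exists for unbalanced designs.
* **Surface/depth pairs.** Whether paired samples at a station count as
  one or two observations is left to the data owner via `group_key`;
  nothing is pooled implicitly.
* **"Wald's method".** The printed field intervals match the modified
  Wald, not the plain Wald; the package implements both under explicit
  names and defaults to the modified form.

## Known limitations

* **Rank-10 instability.** The gap between the 10th and 11th ranked taxa
  is the spacing of adjacent order statistics and is frequently within
  sampling noise. Exact recovery of a planted top-ten set is therefore
  unreliable even when every dominance and classification decision is
  correct — leave-one-out stability in simulated studies (~80–90%
  identical) mirrors the 61–100% seen across field habitat datasets, with
  differences almost always at rank 10. Conclusions that depend on the
  identity of the marginal eDDS should use the leave-one-out report, not
  the point profile.
* **Single stray reads of rare taxa.** For a taxon with run total below
  `1/threshold` reads (1 000 at the default 0.1%), the filter's cut is
  below one read, so a single jumped read of a rare taxon survives. This
  is inherent to run-total-relative filters; the filter's guarantees apply
  to taxa abundant enough that the cut exceeds integer resolution.
* **Cross-suppression.** A taxon genuinely present but locally rare in one
  survey of a multiplexed run can fall below 0.1% of its combined run
  total and be erased there. Filtering per run (not per pooled study)
  keeps this conservative.
* **Unit mixing.** Profiles built from copies are routinely applied to
  reads, weights, or individuals; this is by design (proportions only) but
  inherits gear catchability and PCR bias differences between units.

## Problem sizes

The test suite and the acceptance script run the default study design
(3 habitats × 18 samples × ~50k reads), 50 and 25 replicate studies
respectively for recovery rates, 100-seed envelopes for the concordance and
tag-jump properties, and enumeration-vs-Monte-Carlo cross-checks on 20
random small contingency tables — a few minutes end to end on one core.
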