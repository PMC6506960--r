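---
title: "Within-sample co-methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-sample co-methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometh)
```

## The question and the data

Within-sample co-methylation is the tendency of nearby CpG sites on one
chromosome of a single sample to carry similar methylation levels. `cometh`
quantifies this from standard whole-genome bisulfite sequencing (WGBS)
per-CpG tables — chromosome, 1-based position, sequencing coverage and MC
ratio (methylated reads / total reads, the sequencing analogue of an array
beta value) — and asks two comparative questions: do different individuals'
samples of the same tissue share a co-methylation pattern, and do different
tissues of one individual?

Only the forward strand is modeled; "consecutive" CpGs are adjacent sites on
that strand with no CpG between them. Coordinates in the native tables are
1-based inclusive; BED export converts to 0-based half-open, extending the
end by 1 bp so the interval covers the G of the final CpG. The position
column is taken to refer to the C of the dinucleotide.

## Discretization into methylation states

MC ratios are discretized into four states:

| state | MC ratio | meaning |
|-------|-----------|--------------|
| A | [0, 0.25) | no/low methylation |
| B | [0.25, 0.5) | low/partial |
| C | [0.5, 0.75) | partial/high |
| D | [0.75, 1] | high/full |

Intervals are half-open with the upper bound 1 closed into D, so
`assign_state` is a total, monotone function of the ratio. Sites with
coverage below `min_coverage` (default 3, i.e. under 3X) or with no reads at
all are assigned `NA` — too little evidence to call a state. The threshold is
configurable; `min_coverage = 0` disables the filter entirely, which is how
the worked seven-row example in the test suite (which includes a 2X site
with a called state) is reproduced exactly. We apply the strict under-3X
rule by default and treat that example row as an illustration quirk.

## Analysis 1: state transitions and distance decay

Adjacent CpGs form a *methylation state pair* (initial state, terminal
state, gap in bp). A pair is dropped when either member is `NA`, and pairs
never bridge across an `NA` site: adjacency is positional, so skipping a
masked site would fabricate a "consecutive" pair with a CpG between its
members.

Per sample, `count_transitions` tabulates the 4×4 pair counts and row
percentages (count / row total × 100). `bin_transitions_by_distance`
stratifies pairs into the half-open bins [0, 50), [50, 100), …, [450, 500),
[500, ∞) and computes per-bin percent occurrence. Two denominators are
meaningful: the bin's total pair count (all 16 pair types; the default) or
the bin's row total (conditioning on the initial state, as the marginal
table does). Both are implemented — `profile_table(..., "row-total")` — since
the descriptive layer can reasonably be read either way; the bin-total
default makes the 16 profiles sum to 100 in every bin.

Samples are compared per initial state: the rows of each sample's transition
table for that state are stacked into an r×4 contingency table and tested
with Pearson's chi-squared (no continuity correction; expected counts
`row×col/grand`; df `(r−1)(c−1)`). Because the statistic decomposes exactly
into per-cell `(O−E)²/E` terms, `cell_contributions` attributes the overall
difference to individual samples and state pairs, which is how an outlier
tissue is spotted before its removal is re-tested via the `exclude`
argument (removal is a user decision informed by the contributions, not an
automatic rule).

WGBS contingency tables hold millions of pairs, so even trivial differences
are "significant". The `sensitivity_scan` divides all counts by 10, 100 and
1000 and re-tests, asking whether significance survives at realistic sample
sizes. Counts are re-rounded to the nearest integer (halves away from zero)
by default; `rounding = "none"` keeps fractional counts, under which the
Pearson statistic is exactly homogeneous (X²(O/n) = X²(O)/n) — a property
the tests verify. Scaled tables whose expected counts drop below 5 are
flagged as unusable; a table that degenerates entirely (zero rows/columns
after rounding) yields a flagged `NA` result rather than an error, and
all-zero rows or columns are dropped with a matching df reduction.
P-values that underflow double precision are stored as the smallest
representable positive value and displayed as `~0`.

Pairwise follow-up tests (one 2×4 test per sample pair) run when the
omnibus p-value falls below `alpha` (default 0.05), or always with
`force_pairwise`. No multiplicity adjustment is applied by default, to keep
the follow-ups interpretable as simple decompositions of the omnibus
result; Benjamini–Hochberg adjustment is available via `p_adjust = "BH"`.

## Analysis 2: similarly methylated regions

A *similarly methylated region* (SMR) is a maximal run of consecutive CpGs
sharing one state. `NA` sites break runs (consistent with the pairing rule;
`na_breaks = FALSE` offers NA-transparent runs as a sensitivity check). Runs
need at least `min_count = 2` CpGs to be reported — a single site is not a
region. Each SMR records its CG count and its length,
`last_position − first_position`, which equals the sum of member-to-member
gaps; the shortest reportable SMR (adjacent `CGCG`) therefore has length
2 bp, the minimum the summaries should display.

`summarize_smrs` reports min, Q1, median, mean, Q3 and max per state and
metric. Because a chromosome-scale maximum can be an extreme outlier (D
runs can span tens of kilobases), exactly one occurrence of the maximum is
removed first when `drop_largest = TRUE`; the trimming is applied
independently to the count and length metrics. Quartiles use linear
interpolation between order statistics (`quantile` type 7, the default
convention of most analysis environments).

Count and length distributions are compared across samples with the
Kruskal–Wallis rank test (`stats::kruskal.test` behind `kruskal_wallis`),
always tie-corrected — SMR counts are massively tied at 2 and 3, so an
uncorrected H would be materially wrong. P-values use the chi-squared
approximation with k−1 df; group sizes here are in the thousands, so exact
small-sample p-values are unnecessary. Pairwise two-group tests (df 1)
follow the same conditional-on-omnibus workflow as Analysis 1. The
degenerate all-values-identical case returns H = 0, p = 1 rather than
failing on the vanishing tie correction.

## The synthetic generator

Real Roadmap-scale tracks are not redistributable inside a package, so
every stage is exercised against a generative model with known ground
truth (`sim_config` / `simulate_track`):

* **positions** — fixed spacing, or a shifted geometric gap (minimum 2 bp,
  the spacing of adjacent `CGCG`); the default mean of 100 bp approximates
  the density of forward-strand CpGs on human chromosome 1 (~2.3 M sites
  over ~249 Mb);
* **latent states** — a Markov chain whose kernel relaxes with the realized
  gap d from a base matrix T₀ toward its stationary distribution π:
  T(d) = w·T₀ + (1−w)·**1**πᵀ, w = exp(−d/λ). This is the simplest
  mechanism that yields both realistic marginal transition tables and the
  observed distance decay of co-methylation; λ defaults to 300 bp, within
  the few-hundred-bp range over which human co-methylation is strong before
  deteriorating beyond ~1–2 kb. T₀ defaults to the published STL001 spleen
  row percentages / 100 (`spleen_transition_counts`); the eight
  tissue matrices (`tissue_transition_percentages`) support multi-tissue
  scenarios;
* **emission** — the MC ratio is uniform within the latent state's
  interval, optionally shrunk inward by `emission_margin` so that at high
  coverage discretization returns exactly the latent state;
* **reads** — coverage is Poisson (mean 30, Roadmap-like) truncated at ≥1,
  with an independent 5% zero-coverage probability (about 95% of real
  sites have ≥1X); methylated reads are Binomial(coverage, true ratio).

One master seed drives all draws, so a config plus seed reproduces a track
byte-for-byte. `recovery_report` compares pipeline estimates against the
latent truth: per-distance-bin transition-percentage deviations and the
latent-vs-observed state confusion matrix.

What the generator does *not* emulate: CpG-density heterogeneity (islands
vs deserts), strand asymmetry, non-CpG methylation, regional coverage bias,
and biological emission distributions (a beta-like concentration at 0 and
1). Passing recovery tests therefore demonstrate correctness of the
pipeline's accounting, not that real tissues follow this generative model.

## Verification conditions and problem sizes

The recovery checks run the generator in its noise-free limit — mean
coverage 500, no uncovered sites, emission margin 0.05 — chosen analytically
before measurement: at n = 500 reads the binomial ratio's standard error is
at most 0.0224, so crossing a state boundary at least 0.05 away has
probability ≤1.3% at the worst interior point and well under 1% averaged
over the uniform interior. Under these conditions, with fixed 20 bp spacing
and λ = 10⁶ bp (an effectively homogeneous chain), a 100,000-site track
recovers T₀'s row percentages within 2 percentage points per cell and
matches latent states at ≥99% of sites. Oracle-agreement checks (run-length
segmentation, Pearson and Kruskal–Wallis formulas) each use 1,000 random
cases under fixed seeds; the default test suite sizes its simulated cohorts
at 1,000–2,000 sites per track, enough for every structural property while
keeping the suite fast.

Under the default (noisy, 30X) settings, state misclassification at
interval boundaries is common — latent-state agreement around 85–90% — and
the observed transition table is visibly smoothed relative to T₀. That is a
faithful feature of ratio discretization at moderate coverage, and it is
why comparative conclusions should rest on the statistical layer rather
than on raw percentages.

## Known limitations

* Tracks are single-chromosome by construction; multi-chromosome analyses
  concatenate runs per chromosome upstream.
* The divide-by-10ⁿ scan's integer rounding rule is a convention
  (nearest, halves away from zero); down-scaled statistics depend slightly
  on it, which is why only the undivided statistics are treated as exact.
* Outlier-sample removal is manual (`exclude`), guided by the contribution
  decomposition; no automatic criterion is imposed.
* SMR calling here is descriptive run-length segmentation within one
  sample, not a statistical DMR caller between samples.
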