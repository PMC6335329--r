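---
title: "Differential co-methylation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-methylation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comethdiff)
```

## The model

`comethdiff` treats a methylation study as a features × samples matrix of
beta values in [0, 1] with a binary case/control phenotype. The analysis
has no fitted model in the regression sense; its object is the matrix of
pairwise Pearson correlations of gene-level methylation, computed
separately within each condition, and the *change* of those correlations
between conditions.

Three assumptions matter:

1. **Beta values arrive normalized.** The package performs no
   normalization, probe filtering, or cell-composition adjustment; its
   statistics inherit whatever technical structure the input carries.
2. **A gene's methylation is the unweighted mean of its probes.** All
   annotated probes contribute equally, whatever transcript region they
   fall in; probes annotated to several genes contribute to each (that is
   what the platform annotation semantics imply, and a `multi_gene =
   "drop"` switch exists for the stricter reading).
3. **Pearson correlation with (n−1)-standardized deviations** is the
   co-methylation measure. No rank-based alternative, no correlation
   p-values, and no multiple-testing machinery are offered: downstream
   classification is by effect size (interval change), not significance.

## The interval scheme and its semantics

Correlations are classified into eight fixed bins of width 0.25. Bins 1–7
are half-open `[a, b)`; bin 8 is closed `[0.75, 1]`, so r = 1 is binnable.
A pair "crosses k intervals" when `|bin_case − bin_control| = k`. That
formalization is pinned by the acceptance tests: rebuilding the published
RA and PD 8×8 tables from their printed counts reproduces all five
published crossing counts (18; 1,893; 15; 2,468; 196,311) exactly, which
no alternative reading (e.g. counting boundary crossings of the interval
*edges*) does.

Undefined correlations — a gene constant across one condition's samples —
are never binned. They are excluded from the transition matrix and counted
in `n_excluded`, so the conservation identity
`sum(counts) + n_excluded = n_pairs` holds on every run. Published global
summary statistics do not state how such pairs were treated; the package
reports the summary over defined pairs together with the excluded count,
rather than guessing.

One published boundary case is worth knowing about: among the nine
reference shared pairs, the CDK20–PLEKHF2 RA correlations (0.458, −0.342)
give |Δ| = 0.800 at printed precision, which a strict `> 0.8` filter
excludes. `filter_by_delta()` is strict, as the selection rule is stated
strictly, and it counts and reports exact-threshold ties via the
`n_boundary` attribute instead of silently resolving them; the unrounded
values presumably exceeded the cutoff.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_distance` | 3 | bins | the published large-change criterion (≥ 3 of 8 intervals ≈ a ≥ 0.5 shift in r at bin granularity) |
| `delta_threshold` | 0.8 | correlation | the published strict cutoff on `abs(r_case - r_control)` |
| `chunk_size` | 512 | genes/block | memory–speed trade-off only; results are identical for any value, which a test enforces |
| `n_bins` (summary) | 40 | bins over [−1, 1] | a 0.05-wide histogram, fine enough to see unimodality |
| `probes_per_gene` | 1 | probes | 450K genes typically carry several probes; analyses here use 3 when exercising aggregation |
| `probe_noise_sd` | 0.01 | beta units | within-gene probe disagreement after normalization is small relative to between-sample spread |
| `beta_range` | (0.05, 0.95) | beta units | keeps simulated values strictly inside (0, 1) with realistic headroom |
| repeatability `n_groups`, `group_size` | 5, 100 | — | the published experiment's design (five disjoint groups of 100 genes) |
| repeatability `sample_sizes` | 2, 5, 10, …, 150 | samples | spans the published 2–150 range on a practical grid |

## The synthetic generator

`generate_dataset()` draws each condition from a multivariate normal with
the assembled target correlation matrix (blocks + injected pairs on an
identity base), then maps each gene into `beta_range` with a per-gene
increasing affine (min–max) rescale. Increasing affine maps preserve
sample Pearson correlations *exactly* — this is the affine-invariance
property the test suite checks to 1e−12 — so bounded beta-like values are
obtained without disturbing the quantity under study. The square root of
the target is taken by eigendecomposition rather than Cholesky so exactly
semi-definite targets remain usable. Non-PSD assemblies (e.g. an
impossible negative equicorrelation) fail by default with the offending
eigenvalue; `repair_psd = TRUE` clips eigenvalues at 1e−10 and
re-normalizes to unit diagonal, and the returned truth records the
repaired matrix.

What the generator deliberately does **not** emulate: the bimodal marginal
distribution of real 450K beta values, batch effects, and cell-type
composition — the dominant confounder in whole-blood methylation. Passing
tests therefore demonstrate that the *pipeline arithmetic* is correct and
that correlation changes of the injected size are recoverable at the
stated sample sizes; they say nothing about whether a correlation change
in real blood data is biological rather than compositional.

The analysis drivers simulate co-methylation modules (blocks of 20 genes
at within-block r between 0.3 and 0.7 covering 100 of 120 genes) because
real methylation data shows pervasive correlation structure — published
global SDs of pairwise r are roughly 0.19–0.26 — and because the
repeatability experiment is only informative when the true pair-correlation
vector has spread: on null data the replicate agreement has nothing to
converge to.

## Numerical choices

- **Two-pass standardization.** Means are computed first, then deviations,
  matching the written formula's semantics; the all-pairs engine then uses
  `tcrossprod` on row-standardized blocks. Values can drift a few ulp past
  ±1 and are clamped to the mathematical range; the scalar `pearson()`
  clamps only within 1e−12.
- **Bin edges.** `findInterval(..., rightmost.closed = TRUE)` implements
  the half-open-with-closed-top convention directly; inputs within 1e−12
  beyond ±1 are clamped before binning, anything further errors.
- **Ordering.** All gene and pair ordering uses C-locale (radix) sorting,
  so pair identity — the lexicographically sorted symbol tuple — and output
  order are platform- and locale-independent. Gene symbols are compared
  case-sensitively as given, with no alias normalization.
- **Full-precision I/O.** Pair tables are written with `%.17g` so
  write→read round-trips are bit-exact; transition percentages are
  computed in full precision and only *printed* to five decimals, matching
  the published table style. (The first published RA percentage cell,
  73.53091, appears truncated rather than rounded — recomputation gives
  73.530919 — so checks against printed cells use a 1e−5 band.)
- **Missing values.** Readers accept `NA`/empty as missing. Aggregation
  fails fast by default with a count of offending cells; `na_action =
  "ignore"` averages available probes, leaving a cell missing only when no
  probe is available. Fail-fast is the default because silent missingness
  would make the transition-matrix totals condition-dependent.
- **Repeatability seeding.** One master seed selects the disjoint gene
  groups; each (group, sample-size) cell derives its own substream seed,
  so curves are reproducible and independent of evaluation order, and the
  two replicate draws within a cell are disjoint by construction (asserted
  at run time).

## Problem sizes

The test suite and acceptance script run entirely on simulated data sized
so that every stochastic check is stable under its fixed seeds: engine
equivalence on up to 100 genes, recovery of an injected distance-4 pair at
2,000 samples per condition over 100 seeds, a null false-positive scan
over ~67,000 pair draws at 300 samples per condition, and 100 seeded
repeatability runs at sizes 5 vs 150. The full 21,225-gene problem
(225,239,700 pairs) is exercised only through its combinatorics and the
published transition tables; the chunked engine streams arbitrary gene
counts, but computing a quarter-billion correlations is a batch job, not a
test.

## Known limitations

- Interval distance is a coarse, threshold-based effect measure; a pair
  moving from r = 0.249 to 0.251 changes bins while 0.0 → 0.24 does not.
  No inferential error control accompanies the classification.
- Correlation changes in whole blood can reflect cell-composition shifts
  between case and control groups; the pipeline neither adjusts for nor
  flags this.
- The cross-disease intersection is on pair identity only by default; the
  stricter same-direction criterion is available via
  `require_same_direction = TRUE` in `intersect_pairs()`.
- The probe→gene annotation shipped with a study defines the gene
  universe; gene counts (e.g. 21,225 from GPL13534) depend on the
  annotation version and are treated as dataset properties, not asserted
  constants.
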