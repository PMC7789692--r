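---
title: "Generating three-way data with planted triclusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating three-way data with planted triclusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricgen)
```

## Why generate three-way data

Triclustering algorithms look for subspaces (I, J, K) of a three-way grid
whose values are mutually coherent. Evaluating such algorithms on real data
is limited to intrinsic measures (homogeneity, statistical surprise)
because the "true" subspaces are unknown. A generator that *plants*
triclusters with known location, coherence, overlap and degradation makes
extrinsic evaluation possible: a found solution can be matched against the
planted one. `tricgen` is such a generator. Its output is a value grid plus
a solution report that is deliberately richer than the grid itself — the
compact representation of every planted tricluster (seed, factors,
templates, permutations) is retained so the clean, pre-degradation value of
any planted cell can be recomputed exactly.

## Coherence models

Every tricluster carries a pattern triple `(P_row, P_col, P_ctx)`.

**Numeric triclusters** follow either the additive model
`a[i,j,k] = c + α_i + β_j + γ_k` or the multiplicative model
`a[i,j,k] = c · α_i · β_j · γ_k`. A `Constant` pattern on a dimension pins
its factors to the neutral element (0 additive, 1 multiplicative); an
`Additive`/`Multiplicative` pattern gives the dimension free factors. In
constant-family triples a `None` dimension receives free additive offsets —
the compact seed-plus-factors form has no way to express "independent
values per index" other than a free factor, and a free offset is exactly
what distinguishes an uncorrelated dimension from a constant one in this
representation.

**Symbolic triclusters** (constant-family only — arithmetic patterns are
meaningless on symbols) are a template seed matrix repeated across
contexts, or one independent seed per context when the context pattern is
`None`. A `Constant` dimension holds its symbol fixed along that dimension;
a `None` dimension is filled with independent uniform draws.

**Order-preserving triclusters** fix one permutation π of a single
dimension such that every fiber along that dimension reads non-decreasing
in π-order, and the same π holds across the whole block (in particular
across contexts, which is what makes the pattern temporal when the ordered
dimension is time). On the context dimension three profiles are available:
`increasing` (π = identity), `decreasing` (π = reversal) and `random`
(π uniform over permutations). These blocks are stored *explicitly*
(values plus π): the seed-and-factor form cannot express an ordering
constraint, and materializing the values guarantees the planted ordering
is exact rather than approximate. Ties are allowed — we require
non-decreasing, not strictly increasing, fibers; with discrete alphabets
strictness would often be unsatisfiable, and an ordering with ties is
still order-preserving for any algorithm that ranks values.

Admissibility follows four rules: some dimension must carry coherence; an
order-preserving dimension forces `None` on the other two; additive and
multiplicative patterns never combine with each other, with `None`, or
with order-preserving; symbolic data rejects arithmetic patterns
altogether. These rules admit 24 triples on numeric data and 10 on
symbolic data, and `validate_triple()` reports the broken rule instead of
raising, so configuration errors are self-explanatory.

## Sampling seeds and factors

The generator must keep every clean planted value inside the alphabet for
*any* requested block shape. The seed `c` is drawn uniformly from the
middle half of the alphabet range, leaving headroom of a quarter range on
each side. Additive factors are drawn uniformly in
`±(range / (2 · max(|I|,|J|,|K|)))`; multiplicative factors in
`[1, (bound/|c|)^(1/3)]` per dimension, where `bound` is the alphabet
extreme on the sign side of `c`. Both models are separable, so the block
extremes are available in closed form; after sampling, the factors are
shrunk toward the neutral element (halving the additive amplitude,
contracting multiplicative factors toward 1) until the extremes fit. If no
non-degenerate assignment fits — a two-letter integer alphabet asked for
additive factors, say — the factors collapse to the neutral value with a
warning: the tricluster degrades to constant rather than leaving the
alphabet. Integer alphabets round seeds and factors, re-verifying after
rounding. Order-preserving values are drawn from the background
distribution restricted to the alphabet (uniform over the alphabet when
the background is the all-missing family), so planted blocks are not
trivially separable from the background by their marginal distribution.

## Structure and placement

Tricluster counts are fixed; sizes are drawn per dimension from uniform or
normal distributions, rounded (half-to-even, the unbiased integerization)
and clipped to `[1, dimension length]`. A contiguous dimension (features
or contexts, for time-series-like data) is a run of consecutive indices
whose start is uniform over the feasible positions.

Placement proceeds in overlap-group order. The first member of a group
samples each index subset independently and uniformly. Each later member
copies a random sub-block of every already-placed partner — per-dimension
shared counts are drawn under the per-dimension caps and then reduced
until the implied shared-cell count fits the pairwise quota
`⌊pct_elements · min(|t₁|, |t₂|)⌋` — and samples its remaining indices
fresh, avoiding partner indices so the realized sharing equals the chosen
counts. Two policies are deliberate design choices:

- **Incidental overlaps are forbidden.** Triclusters not designated to
  overlap never share a cell. The solution report labels overlap exactly,
  and an evaluation against the ground truth would be corrupted by
  unplanned shared cells. Candidates colliding with non-partners are
  rejected and resampled; the context dimension is sampled from the
  non-colliding positions directly to keep rejection rates low.
- **Graceful degradation.** If a tricluster cannot be placed within the
  retry budget (3000 attempts), it is dropped with a warning and the
  maximal placed set is returned. Dense or highly constrained requests
  (many overlapping triclusters with contiguity and tight caps) can be
  genuinely infeasible, and a partial solution with an honest warning is
  more useful than an error.

Overlap groups are formed by marking `⌊n · pct_triclusters⌋` triclusters
as overlapping and splitting them into `⌊·/k⌋` groups of size `k`; a
remainder of one cannot overlap and becomes a singleton, a larger
remainder forms a final smaller group. Within a group an interaction graph
is drawn uniformly among connected labeled graphs (by rejection — groups
are small), spanning the range from pairwise chains to the complete
k-wise clique; the graph is recorded in the solution report.

## Plaid composition

A cell shared by several triclusters takes the sum, product, or average of
the individual contributions, or the value of the last-generated
tricluster (`none` — the only plaid valid on symbolic data). The base term
of the plaid equations is taken as 0: every contribution already carries
its own seed, and a further global offset would double-count without any
principled value to assign it. Composed values can leave the alphabet
(two large additive contributions, say); they are clamped to the range,
because an emitted dataset must be alphabet-valid. Clamping is recorded
nowhere — the solution report stores the *contributions*, from which the
composed value is recomputable.

## Quality injection

Degradation separates exact background control from bounded tricluster
control. On the background (cells covered by no tricluster) exactly
`⌊|B| · pct⌋` cells per category are degraded — floors, never rounding up,
so a user's budget is never exceeded. Inside each tricluster the count per
category is uniform on `[0, ⌊|t| · pct⌋]`: planted subspaces differ in how
damaged they are, which is the realistic regime for stress-testing
noise-tolerant algorithms. The three categories are applied in the order
missing → noise → errors on disjoint cell sets, so every degraded cell has
exactly one label in the report. Cells in overlap regions belong to
triclusters, not the background, for all accounting.

The `noise_deviation` parameter is the boundary between noise and error,
measured as absolute difference on numeric alphabets and rank distance in
alphabet order on symbolic ones. Noise replaces a value by a *different*
value within the boundary (uniform over the admissible set; for real
alphabets a uniform perturbation clamped to the range, redrawn if clamping
lands on the original). Errors go beyond it: inside triclusters, a uniform
draw from the values at distance strictly greater than the boundary (every
such value qualifies, including the alphabet ends), falling back to the
extreme farther from the original when no such value exists; on the
background, the alphabet extreme farther from the expected value of the
background distribution (midpoint for uniform, the mean for Gaussian, the
probability-weighted mean for discrete), with ties broken at random.
Degenerate cases — a singleton noise band, a two-symbol alphabet with zero
deviation — leave the value unchanged with a warning rather than
fabricating an inadmissible replacement.

## Backgrounds and their boundary rules

Uniform backgrounds are discrete-uniform over symbolic/integer alphabets
and continuous-uniform over real ranges. Gaussian backgrounds name a mean
and standard deviation; out-of-range draws are *clamped* to the alphabet
bounds (not resampled): clamping is deterministic, preserves the nominal
center to first order, and its boundary atoms are a fair price for
reproducibility — the generation pipeline is a pure function of
configuration and seed. On symbolic alphabets the Gaussian is interpreted
on the symbol-rank scale and discretized. Discrete backgrounds (one
probability per element) are restricted to symbolic and integer alphabets.
The `missing` family fills everything with the missing sentinel (`NA`),
leaving only planted triclusters visible.

## Serialization

The dataset is written as `|Z|` tab-separated slice blocks, each headed by
`# context <k>`; rows are observations, missing cells are empty fields,
and real values are printed with 17 significant digits so that reading the
file back reproduces the grid bit-exactly. The solution is written as JSON
(schema in `inst/schema/solution.schema.json`) plus a human-readable text
rendering. Externally all indices are 0-based — a fixed, documented
convention for consumers in any language — while the R objects use
R-native 1-based indices internally; the conversion happens only at the
serialization boundary.

## What the generator does and does not emulate

The presets reproduce published benchmark configurations: mimics of five
real-world datasets (gene expression time series, stock ratios, fMRI,
bookmarking triples, daily temperatures), clean base datasets per data
type, scalability series from 10⁶ to 10⁹ cells, overlap and quality
stress variants, pattern-restricted suites, and rich combinations. Two
tabulations of the fMRI mimic's dimensions disagree in their source
material (20 × 464 × 94 vs 20 × 494 × 94); the presets follow the
settings table (494).

Synthetic data of this kind supports *relative* algorithm comparison, not
claims about biology: backgrounds are i.i.d. (no spatial or temporal
autocorrelation outside planted subspaces), noise is homoscedastic,
missingness is completely at random, and planted coherence is exact up to
the injected degradation. Passing a benchmark built on these assumptions
shows an algorithm recovers clean planted structure under controlled
damage — not that it handles the correlated noise, batch effects or
structured missingness of real assays.

## Problem sizes and verification

The test suite verifies, among other properties: exact reconstruction of
every admissible pattern triple over randomized block shapes (brute-force
fiber checks for orderings, termwise model evaluation for factors); plaid
composition recomputed from stored contributions on every overlap cell;
the admissibility set against an independent rule oracle over all 125
triples; exact background degradation counts and bounded tricluster
counts over 1000 seeded repetitions; byte-identical outputs under a fixed
seed; and an end-to-end generation of the 10⁷-cell scalability preset.
Statistical checks (background frequencies, noise-band uniformity) use
central-limit or binomial bounds at 3-5 standard deviations with fixed
seeds. Unit tests run on deliberately small grids (tens of cells to a few
thousand); the scalability smoke test is the one large run.
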