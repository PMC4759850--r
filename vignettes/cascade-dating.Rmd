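---
title: "Cascade strict-clock dating of UCE loci: model, generator, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade strict-clock dating of UCE loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uceclock)
```

## The estimator

`uceclock` implements a deliberately simple, transparent divergence-dating
method for phylogenomic data sets of ultraconserved elements (UCEs): a
*naive strict clock* applied per locus to corrected pairwise Hamming
distances, with calibrations cascading down the tree from a single root
age.

For one locus and one clade, let $d_t$ be the mean corrected p-distance
between the clade's two daughter lineages (all defined cross-pairs,
pairwise deletion of sites with `N`, `-` or `?`), and $d_c$ the same
quantity across the *calibration split* with known (or previously
estimated) age $T_c$. Under a strict clock, distance ratios equal age
ratios, so the locus's age estimate for the clade is

$$\hat T \;=\; T_c \cdot \frac{d_t}{d_c}.$$

Distances are first corrected for multiple substitutions by a uniform
saturation factor, $d \mapsto d / c$ with $c = 0.95$ by default. Because
the estimator is a *ratio* of distances, any uniform factor cancels:
estimates are provably invariant to $c$, and the test suite asserts this
by running the cascade at $c = 0.95$ and $c = 1$ and comparing every age.
The correction matters only if distances are exported and interpreted on
their own scale.

Three per-locus failure modes are distinguished and recorded rather than
silently dropped:

* **`non_clock_like`** — $\hat T > T_c$. A subclade cannot be older than
  the node that contains it, so such loci are discarded as affected by
  incomplete lineage sorting or lineage rate variation. The comparison is
  a *strict* inequality: a locus whose estimate equals its calibration
  (in particular, the calibration split itself) passes.
* **`missing_outgroup`** — no defined pair across the calibration split
  (e.g. the single outgroup genus was not captured at this locus).
* **`undefined`** — no defined pair across the target split, or a zero
  calibration distance (no rate is estimable).

Pairs with fewer than `min_overlap` compared sites (default 100) are
treated as undefined rather than contributing noisy distances.

## The cascade

A `cascade_schedule` anchors at one root calibration — here, the split of
*Mantheyus* from all other draconine genera at 85 MYA — and lists clades
in an order in which every calibration source precedes its dependents.
Each level's calibration age is the *filtered point estimate* of its
source (the median of that source's clock-like per-locus ages; a mean is
available behind `point_estimator = "mean"`), and its per-locus
calibration distance is measured across the source's own defining split
at the same locus. The locus-matched ratio lets each locus carry its own
rate, which is what makes per-locus box-whisker distributions meaningful.
If a source retains no clock-like locus the pipeline stops with a
"cascade starvation" error naming the level — the honest outcome when a
clade is so rate-shifted that nothing survives its filter.

The median was chosen as the propagated point estimator because the
discard rule induces a right-truncation of the per-locus age
distribution; the median is less sensitive to the resulting skew than the
mean, though not immune to it (see *Known biases*).

Clade TMRCAs are operationalized on a fixed topology: the age of a clade
is the mean corrected distance between its two daughter subclades. The
topology is taken as given (as in analyses that constrain relationships
to a genomic tree before dating); the package does not infer trees.

## Rate-shift classification

For each dated clade the pipeline also asks whether its lineages evolve
faster or slower than the sister lineages on the other side of its
calibration split. Depths on either side of the ingroup/outgroup node are
triangulated from distances alone: the mean outgroup depth is half the
mean within-outgroup corrected distance, $b_O = \bar d_{OO}/2$, and the
mean ingroup depth is the mean cross distance minus that,
$b_I = \bar d_{IO} - b_O$. Averaged over loci, a relative difference
$(b_I - b_O)/b_O$ beyond a threshold (default 0.05, exposed in the
configuration and echoed in the output) is called a `speed_up`; beyond
the threshold in the other direction, a `slow_down`.

Two caveats are intrinsic to this construction and are reported rather
than hidden:

* With a **single outgroup taxon** triangulation is impossible. The
  outgroup depth falls back to half the calibration-split cross distance
  — which assumes the very clock being tested — and the call is flagged
  `approximate`.
* $b_O$ estimates the outgroup's **average coalescent depth**, not its
  depth at the ingroup/outgroup node. When the outgroup's crown is much
  younger than that node, $b_O$ understates the true depth and the call
  is biased toward `speed_up` even under a perfect clock. The call is
  therefore most trustworthy where the sister clade's crown sits close to
  the calibration node (in the Draconinae fixture: group 4 versus
  *Salea*+*Calotes*, crowns at 56 vs a node at 57); elsewhere, read the
  reported $b_I$ and $b_O$ values rather than the label alone. No
  distance-only correction can remove this bias: the outgroup's stem
  length is unidentifiable without an external reference taxon, and
  rescaling by cascade-estimated ages provably degenerates to
  $b_O = \bar d_{IO}/2$ (the correction and the signal cancel exactly).

## The synthetic UCE generator

The generator exists so the whole pipeline can be validated against known
truth without access to the original capture data. It emulates the
statistical shape of a published draconine UCE matrix:

| Parameter | Default | What it emulates |
|---|---|---|
| `length_mean`, `length_sd` | 644.7, 249.7 bp | locus length distribution (draws clamped at `length_min` = 100 bp) |
| `site_rate` | 6.31e-4 subs/site/MY | chosen so the expected root-split (85 MYA) p-distance is 0.10; yields ~10 % parsimony-informative sites |
| `missing_fraction_mean`, `sd` | 0.236, 0.194 | per-locus missing data, realized as terminal runs of `N` (ragged ends) |
| `missing_individual_prob` | 0.10 | whole-individual dropout, hard-capped at 25 % of taxa per locus |
| `pop_size` (msc) | 1 MY | expected within-population pairwise coalescence time |

Design notes, in the order the data are built:

* **Fixture tree.** The 17-genus Draconinae time-tree with the root at
  the 85 MYA calibration value (keeping recovery experiments
  self-consistent; the corresponding Bayesian point estimate of the root
  is older, which we record as an open question, not a bug). Nodes
  without a published age are placed midway between their parent and
  their oldest dated descendant; the one ambiguous resolution inside
  group 1 (the order of *Japalura* and *Pseudocalotes*) is fixed
  arbitrarily and documented in `?build_fixture_tree`.
* **Gene trees.** `ils_mode = "none"` uses the species tree unchanged;
  `"msc"` draws one genealogy per locus under the multispecies
  coalescent (one haploid sample per tip, coalescence rate
  $k(k-1)/2/N$ within each species branch). As `pop_size` approaches 0
  the gene trees converge on the species tree, which the tests use as a
  limit check against the strict-clock run.
* **Sequences.** Site-independent evolution along the gene tree (JC by
  default, HKY optional) via `phangorn::simSeq`, with branch lengths in
  expected substitutions per site. Clock modes: `strict`;
  `per_locus_lognormal` (mean-1 lognormal locus rate factors); and
  `branch_multipliers`, which scales every branch inside a named clade's
  crown group — the tool used to manufacture known rate shifts.
* **Missing data.** The per-locus missing fraction is drawn from a Beta
  distribution moment-matched to mean 0.236 and SD 0.194. A clamped
  normal with those moments (the obvious alternative) has mean ≈ 0.246 —
  it cannot reproduce the target mean, whereas the Beta has exactly the
  right moments and the right support for a fraction. The fraction is
  measured over the sequences *present* at the locus and realized by
  masking terminal runs at randomly chosen ends, which deliberately
  stresses the pairwise-deletion overlap logic the way ragged capture
  contigs do. Individual dropout is an independent channel, tracked in
  the truth table.
* **Reproducibility.** One master seed; each locus and stage uses a
  derived substream, so any subset of loci is reproducible in isolation.
  The substream seed is scrambled through one intermediate draw before
  use because adjacent Mersenne-Twister seeds produce measurably
  correlated early output — enough to distort generator moment checks.

What the generator does **not** model: indels and alignment error,
probe-capture bias (missingness here is independent of divergence),
within-genus sampling (one haploid sequence per genus by default),
base-composition heterogeneity across lineages, and gene flow. Passing
recovery tests therefore show that the pipeline's logic is correct under
its own assumptions — not that real UCE data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Quantiles in the five-number summaries use linear interpolation
  (type 7): on ages 1..4, Q1 = 1.75 and Q3 = 3.25; tests pin this against
  a brute-force sort-and-interpolate oracle.
* The age is computed as $T_c \times (d_t/d_c)$ — ratio first — so the
  calibration split itself returns $T_c$ bit-exactly and cannot be
  misclassified by a final-ulp rounding artifact.
* Ultrametricity of input trees is checked at a relative tolerance
  (default 1e-6) and violations name the worst tip pair.
* All-missing present sequences, ragged alignments, duplicated taxa,
  overlapping daughter sets, and forward calibration references are
  rejected at construction time with named errors.
* An all-identical data set (zero distances) produces `undefined` records
  and a cascade starvation error, not ages.

## Validation and problem sizes

The test suite validates the pipeline end to end at sizes chosen to keep
a full run in minutes on one CPU: parameter recovery on 1000 strict-clock
loci (every fixture clade's point estimate within ±15 % of truth;
typically within ±5 % for clades whose true age is well below their
calibration, see below), generator moment recovery on 10000 loci (mean
length and mean missing fraction within two standard errors of the
configured values), calibration exactness, correction-factor invariance,
brute-force oracles for group distances and quantiles, rate-shift
sensitivity (a ×2 rate multiplier inside group 4 drives its
non-clock-like fraction above one half and a `speed_up` call), and the
coalescent small-population limit.

## Known biases and limitations

* **Filter-induced underestimation.** Discarding loci with
  $\hat T > T_c$ right-truncates the age distribution. When a clade's
  true age is close to its calibration (e.g. *Salea*|*Calotes* at 56
  versus a calibration node at 57) and its target distance rests on a
  single taxon pair, nearly half of the upper tail is discarded and the
  median of the surviving loci shifts down by roughly 10–15 %. This is a
  property of the method, visible in our recovery runs and consistent
  with the tendency of naive strict-clock estimates to undershoot;
  treat cascade ages near their calibration as lower-leaning.
* **No among-lineage rate correction.** A genuinely rate-shifted clade
  does not get a corrected age; it gets flagged (non-clock-like
  fractions, rate-shift call) and, in severe cases, starves its
  dependents. That is intended behavior, not robustness.
* **Saturation.** The uniform correction cancels in ratios, so residual
  saturation curvature biases shallow-over-deep ratios slightly upward;
  at the default rate (root p-distance 0.10) the effect is within a few
  percent and shrinks with the rate.
* **Reference ages** (e.g. from a Bayesian relaxed-clock analysis) are
  annotation-only inputs for comparison columns; the package never
  computes them.
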