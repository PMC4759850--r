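# uceclock

Distance-based strict-clock divergence dating for ultraconserved-element
(UCE) phylogenomic data, with cascading node calibrations, clock-like
locus filtering, lineage rate-shift classification, and a synthetic UCE
data generator for validation against known truth.

## Who this is for

Phylogeneticists who have (i) per-locus UCE alignments for a set of taxa,
(ii) a fixed, rooted topology with one well-supported calibration age at
the root, and (iii) a need for fast, transparent per-locus divergence-time
estimates — either as a cross-check on relaxed-clock Bayesian dating or as
a first look at rate heterogeneity across loci and lineages. The package
was built around a genus-level data set for the agamid lizard subfamily
Draconinae (17 genera, root calibration 85 MYA) which ships as the default
fixture, but every component takes arbitrary trees, clade tables and
cascade schedules.

## The method

For one locus and one clade with daughter lineages $A$ and $B$, the
estimator is a naive strict clock on corrected Hamming distances:

$$\hat T \;=\; T_{\mathrm{cal}} \cdot \frac{d(A,B)}{d(C_1,C_2)}$$

where $d(\cdot,\cdot)$ is the mean pairwise p-distance across groups
(pairwise deletion of `N`/`-`/`?` sites, uniform saturation correction
$d/0.95$, which cancels in the ratio), and $(C_1, C_2)$ is the calibration
split with age $T_{\mathrm{cal}}$. Calibrations cascade: the root split is
calibrated externally (85 MYA by default), each subsequent clade is
calibrated by the filtered median of an earlier clade's per-locus ages.
Loci whose estimate exceeds their calibration are discarded as
non-clock-like (incomplete lineage sorting or rate variation); loci
lacking the calibration-side taxa are reported as missing-outgroup.
Per-clade output is a five-number summary, status fractions, a point
estimate, and a rate-shift call triangulated against the sister lineages.

The synthetic generator simulates UCE matrices with the statistical shape
the method expects — locus lengths 644.7 ± 249.7 bp, ~10 % parsimony-
informative sites, per-locus missing data 23.6 % ± 19.4 % realized as
ragged ends, up to 25 % missing individuals per locus, optional
multispecies-coalescent gene-tree discordance and per-clade rate
multipliers — so every claim the pipeline makes can be tested against
ground truth. See the vignette (`vignettes/cascade-dating.Rmd`) for the
model, its assumptions, and its known biases.

## Worked example

Simulate 300 strict-clock loci on the Draconinae fixture tree, date them,
and compare with the fixture's true node ages:

```r
library(uceclock)

cfg <- sim_config(n_loci = 300, seed = 42)
ds  <- simulate_dataset(cfg)
res <- run_cascade(ds$loci)
print(res)
```

```
<cascade_result> 10 clades, 300 loci
  Draconinae         point   85.00 MYA  (T_cal   85.00 from ROOT;  85% clock-like)
  NonMantheyus       point   68.77 MYA  (T_cal   85.00 from ROOT;  75% clock-like)
  DracoPtyctolaemus  point   52.31 MYA  (T_cal   68.77 from NonMantheyus;  69% clock-like)
  Groups1to4         point   58.33 MYA  (T_cal   68.77 from NonMantheyus;  86% clock-like)
  Group1             point   51.39 MYA  (T_cal   58.33 from Groups1to4;  56% clock-like)
  Groups234          point   53.62 MYA  (T_cal   58.33 from Groups1to4;  62% clock-like)
  SaleaCalotes       point   49.18 MYA  (T_cal   53.62 from Groups234;  35% clock-like)
  Group4             point   46.67 MYA  (T_cal   53.62 from Groups234;  76% clock-like)
  ABG                point   37.47 MYA  (T_cal   46.67 from Group4;  66% clock-like)
  SriLanka           point   25.90 MYA  (T_cal   46.67 from Group4;  78% clock-like)
```

Reading this: the root-calibration split (`Draconinae`) returns exactly
85 MYA for every locus at which it is defined — a built-in sanity check.
`NonMantheyus` (true age 69) is recovered at 68.8 MYA with 75 % of loci
clock-like; the 15 % missing-outgroup loci are those where the single
outgroup genus *Mantheyus* was dropped by the simulated capture process.
Clades whose true age presses against their calibration (e.g.
`SaleaCalotes`, true 56 vs calibration 53.6 here) lose many loci to the
clock filter and their medians lean low — the characteristic
underestimation of this class of methods, quantified in the vignette.

A per-clade report with a comparison column against reference ages:

```r
tr   <- ds$species_tree
refs <- setNames(vapply(names(res$summaries), clade_age, 0, tree = tr),
                 names(res$summaries))
cmd_report(res, reference_ages = refs)
#>          clade point_estimate    min    q1 median    q3   max  pct_clock_like ...
#>   NonMantheyus          68.77 47.614 64.01  68.77 73.86 84.08           75.33
#>     Groups1to4          58.33 39.847 53.96  58.33 62.55 68.46           86.33
#>       SriLanka          25.90  6.937 21.78  25.90 29.98 45.73           77.67
#>   ...                                          reference_age abs_difference
#>   ...                                                     69         0.2315
```

The same pipeline is available from the shell via the thin CLI at
`inst/scripts/uceclock` (`simulate`, `date`, `report` subcommands), which
writes per-locus TSV records, JSON clade summaries, and a provenance
record beside every output.

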