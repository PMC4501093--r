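---
title: "Separating serial-founder drift from climate signals in risk-allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating serial-founder drift from climate signals in risk-allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Worldwide allele-frequency data carry a strong demographic signature: each
founding event along the out-of-Africa expansion resampled the gene pool,
so expected heterozygosity declines approximately linearly with migration
distance from East Africa. Any panel of SNPs — including GWAS risk panels
for complex diseases — inherits this decline whether or not selection ever
acted on it. The question this package addresses is therefore not "do risk
allele frequencies vary geographically?" (they must) but "do they vary
*more in the direction of a climate variable* than frequency-matched
random SNPs that experienced the same demography?"

`alleleclim` implements the full chain of that comparison: allelic summary
statistics, drift baselines, waypoint-routed migration distances,
regressions, frequency-matched resampling nulls with empirical p-values,
per-SNP environmental score post-processing, tail-enrichment permutation
tests, and gene annotation — together with a synthetic-data generator that
reproduces the statistical structure the analysis assumes, so the whole
pipeline is testable end to end without any external download.

## Statistics and model

For a disease with $d$ risk SNPs and risk-allele frequency $p_{ij}$ of SNP
$i$ in population $j$ (with $q_{ij} = 1 - p_{ij}$), the two per-population
panel statistics are the average heterozygosity

$$ H_j \;=\; \frac{1}{d}\sum_{i=1}^{d} 2\,p_{ij}q_{ij} $$

and the average risk-allele frequency $\bar p_j = \sum_i p_{ij}/d$. When
the stored (designated) allele is not the risk allele, the frequency is
complemented before averaging; heterozygosity is orientation-invariant.

The same two statistics computed over *all* SNPs in the matrix form the
genome-wide baseline. Subtracting the baseline from the panel statistic
("adjusted" statistics) removes the component of variation shared with the
whole genome — the drift signature — leaving the panel-specific residual.
The pipeline's convention, selectable per call, is to regress **raw**
statistics on migration distance (where drift itself is the hypothesis)
and **adjusted** statistics on climate variables (where drift is a
nuisance); both variants are available for every predictor because the
distance regression is also meaningful in adjusted form.

Distances are haversine great-circle distances on a sphere of radius
6371.0 km, routed through migration waypoints (origin Addis Ababa;
waypoints Cairo, Istanbul, Anadyr, Phnom Penh, Prince Rupert). The
region-to-route assignment ships as an editable table
(`default_route_table()`); the waypoint-to-region mapping for real
population panels is not uniquely fixed by convention, so it is
configuration, not code.

### The resampling null

A panel's R² against a predictor is only interpretable relative to what
random SNPs of the same frequency profile achieve. All SNPs are binned by
global allele frequency (unweighted mean over populations) into ten
half-open bins $[0, 0.1), \dots, [0.9, 1.0]$; each null set replaces every
risk SNP by a uniform draw from its bin, excluding the disease's own risk
SNPs and without within-set duplicates. (Exclusion and no-duplication are
this package's choices; at pool
sizes of $10^4$–$10^5$ SNPs per bin they are numerically immaterial, and
exclusion prevents a null set from trivially reproducing the observed
panel.) Each resampled set is pushed through the identical
profile-adjust-regress pipeline; the default design uses 10,000 sets. One
pool of resampled sets serves all ten predictors and both statistics for a
disease, so the per-predictor null distributions are deliberately
dependent — keeping every predictor comparable on the same resamples and
saving a factor of ten in compute — while different diseases get
independent pools.

The empirical p-value is the fraction of null sets with *strictly* higher
R²; ties count as not higher, and 0 is an attainable value. A
$(k+1)/(n+1)$ estimator is available behind a flag for users who need
p-values bounded away from zero.

Multiplicity is controlled per disease over 10 predictors × 2 statistics:
Bonferroni at $0.05/20 = 0.0025$ (strict), and Benjamini–Hochberg at an
FDR of 0.2. Both thresholds are configurable.

### Per-SNP scores and tail enrichment

Per-SNP environmental-association scores (Bayes factors from an external
scan, or this package's correlation surrogate for synthetic data) are
post-processed in the fixed order *average runs → combine ascertainment
panels → rank*; the order matters because ranking does not commute with
averaging or concatenation, and a property test asserts exactly that. The
ranked p-value of SNP $i$ for variable $v$ is
$\#\{k : s_{kv} \ge s_{iv}\}/N$ — ties share the larger count, the most
conservative convention — which is invariant under any strictly increasing
transform of the scores, so only score *ranks* ever matter downstream.

Tail enrichment of a disease in the $p < 0.05$ tail is

$$ \mathrm{enrichment} \;=\; \frac{n_r / n_{nr}}{N_r / N_{nr}}, $$

with $n_r, n_{nr}$ the risk / non-risk SNPs in the tail and $N_r, N_{nr}$
the totals. Its significance comes from 50,000 (default) random same-size
SNP sets drawn from all scored SNPs (risk SNPs included — the simpler and
slightly conservative reading of "random SNPs"); the permutation p is the
fraction of sets with strictly *more* tail SNPs than observed. The default
significance cutoff is the grid-level Bonferroni value 0.00026
(≈ 0.05/189 for 21 diseases × 9 variables), overridable for other grids.

### Gene annotation

A SNP is genic if it lies within 10 kb of a gene's merged
(min-start/max-end across isoforms) interval, strand ignored, computed in
0-based half-open coordinates with GenomicRanges. Measuring from the
merged envelope rather than per-isoform bounds is a choice; the
alternative changes only SNPs in the 10 kb flanks of inner isoform ends.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Drift**: pure binomial resampling of $2N_e$ gametes per founding
  event, no mutation, migration or selection. Expected heterozygosity then
  decays by exactly $1 - 1/(2N_e)$ per event, giving the linear-in-distance
  decline the regressions target. Reference conditions: 60 populations,
  20,000 SNPs, $N_e = 500$ (per-event retention 0.999), one event per
  step, 400 km between neighbours (a chain span of ~24,000 km, the order
  of the out-of-Africa expansion), ancestral frequencies uniform on
  $[0.05, 0.95]$ to avoid immediate fixation.
* **Climate**: nine named variables on standardized scales, each
  `loading × z(distance) + noise`. Longitude loads strongly (0.8, noise
  0.6 — migration ran mostly across longitudes), latitude and temperatures
  moderately (±0.3–0.5), and precipitation/humidity weakly or not at all,
  so both distance-confounded and distance-independent predictors exist.
  Physical units are irrelevant to correlation-based analyses, so none are
  modelled.
* **Clines**: an additive frequency shift `clamp(p + β z + ε, 0, 1)` on a
  chosen SNP set, with β = 0.1 per SD and ε ~ N(0, 0.02) as reference
  effect size. This is an effect *generator*, not a selection model: the
  downstream statistics see only the induced frequency–environment
  correlation, which is all they are designed to detect.
* **Panels**: disjoint random SNP sets with the 21 standard panel sizes
  (7–41), optionally pinned to cline-injected SNPs.

What the generator deliberately omits — linkage disequilibrium,
ascertainment bias, admixture, mutation, realistic coalescent noise —
bounds what passing tests show: they demonstrate that the statistical
machinery is correct and calibrated under the model's own assumptions, not
that those assumptions hold for any particular real data set.

## Numerical and design choices

* **Frequency bins** are half-open with the top bin closed
  ($[0.9, 1.0]$), so frequency 1.0 is binnable and 0.1 falls in
  $[0.1, 0.2)$.
* **Degenerate inputs fail fast**: missing frequency cells, out-of-range
  values, constant predictors, sub-3-population subsets, empty panels and
  exhausted bin pools are errors naming the offending item, not silent
  repairs. A constant *SNP row* in the score surrogate scores 0 rather
  than erroring, since genuinely monomorphic SNPs occur in real matrices.
  The enrichment ratio returns `NA` (flagged, not thrown) when a
  denominator vanishes.
* **WLS weights** are inverse variances of the panel-mean frequency
  (sample variance across the $d$ SNPs divided by $d$); the raw sample
  variance is available via `type = "sample"` because the convention is
  ambiguous and both readings are defensible.
* **Collinearity** is a documented pre-analysis report
  (`predictor_correlations()`, default flag at |r| ≥ 0.99, the
  latitude-vs-summer-radiation situation) rather than hard-coded variable
  removal.
* **Seeds**: one master seed; per-stage substreams are derived by a fixed
  integer recurrence kept below $2^{31}$, so any stage can be rerun
  independently and the whole pipeline is byte-reproducible. Null
  distributions are cached as full-precision TSVs (17 significant digits,
  which round-trips IEEE doubles exactly).
* **Test scale**: validation runs use 1,000 resampled sets and 1,000–5,000
  permutations instead of the full-scale 10,000/50,000. The statistics are
  identical; only Monte-Carlo resolution changes, and the calibration
  checks account for the coarser p-value granularity (below).

### Calibration subtleties worth knowing

Two discreteness effects matter when validating with 1,000 resampled sets.
First, the Bonferroni threshold 0.0025 admits empirical p-values
$\{0, 0.001, 0.002\}$, a realized level of $3/1001 \approx 0.003$ — the
neutral flag rate is checked against that attainable level, not the
unattainable nominal 0.0025. Second, because one pool of resampled sets
serves all ten predictors, a disease's ten p-values are dependent; a
pooled Kolmogorov–Smirnov test of uniformity across predictors would
overstate its effective sample size, so the calibration check pools one
predictor per experiment (rotating across the ten), yielding 200
independent p-values. Per-predictor marginals are uniform, which is the
property the null construction must deliver.

For the enrichment permutation test the same logic fixes the calibration
design. Because the permutation p counts strictly-greater tail counts, it
forgoes the tie-inclusion that makes an exact randomization test
conservative: its true level is the attainable tail probability just
*above* 0.05, plus a small Monte-Carlo smoothing term at finite
`n_perm`. Computing that level exactly (hypergeometric tail counts ×
binomial Monte-Carlo noise) across candidate designs shows it is
minimized — about 0.06 — for panels of several hundred random labels
over a 4,000-SNP scored pool; the calibration uses 400. Tiny panels
(7–41 SNPs) are worse in both directions: their tail counts of 0–2 make
the level lurch with each lattice point. The residual mild
anti-conservatism is a property of the strict comparison itself, which
is retained because it is the test's defining convention.

## Known limitations

* The surrogate score is a stand-in with the right invariances (rank-based
  downstream, top-tail concentration for injected clines), not a
  reimplementation of a Bayesian allele-environment model; real analyses
  should feed externally computed Bayes-factor tables through
  `read_score_table()`.
* Spatial autocorrelation among populations is not modelled; populations
  enter regressions as independent points.
* No LD-aware resampling: null SNPs are matched on frequency only.
* Climate is a linear function of distance plus noise in the generator;
  non-monotone real-world climate geography (e.g. humidity maxima at the
  equator) is not emulated.
* The waypoint route table resolves region-level, not per-population,
  routing; real-data distances can differ slightly under other plausible
  mappings.
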