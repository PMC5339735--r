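---
title: "Quantifying the robustness of epigenomic marks across replicates"
author: "epirobust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the robustness of epigenomic marks across replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirobust)
library(SummarizedExperiment)
```

## The question this package addresses

Environmental or experimental conditions may leave the *mean* level of an
epigenetic modification untouched while changing how *reproducibly* that
level is established across biological replicates. epirobust implements a
tile-based analysis that asks both questions for histone ChIP-seq data and
for two-channel methylation arrays:

1. **Differential enrichment** — does the mean signal differ between two
   conditions? (negative-binomial GLM likelihood-ratio test per tile;
   moderated t per CpG probe), and
2. **Differential robustness** — does the replicate-to-replicate
   variability differ? (squared coefficient of variation, CV², of
   normalized tile counts; replicate variance of M-values), compared by
   Wilcoxon rank-sum tests and stratified by genomic feature class,
   chromatin bivalency and differentiation dynamics.

Everything runs on synthetic data with known ground truth, generated by
the package's own seeded simulators, so every stage is testable without
external downloads.

## The count model

Tile counts are modeled as negative binomial with the edgeR-style
parameterization

$$\operatorname{Var}(Y) = \mu + \phi\,\mu^2,$$

where $\phi \ge 0$ is the dispersion; $\phi = 0$ is the Poisson boundary.
Sample $j$'s expected count in tile $i$ is $\mu_{ij} = \beta_i f_j$ with
library-size offsets $f_j = \text{libSize}_j/10^6$, so fitted coefficients
are on the counts-per-million scale. The null model fits one coefficient
per tile, the alternative one per group, and the statistic
$2(\ell_1-\ell_0)$ is referred to $\chi^2_1$.

**Dispersion estimation.** A per-tile maximum-likelihood dispersion at two
or three replicates per group is biased severely downward, and the
$\chi^2_1$ reference then yields a type-I error near 0.13 at the nominal
0.05 — one can see this analytically in the Gaussian limit, where the bare
LRT corresponds to referring an $F(1,4)$ statistic to a $\chi^2_1$
cutoff. We therefore estimate $\phi$ per tile by the Cox–Reid adjusted
profile likelihood (APL) and moderate each tile's APL toward the mean APL
over all tiles with a prior weight of `priorDf / residual df`
(`priorDf = 20` by default). This is the weighted-likelihood
empirical-Bayes scheme standard in count-GLM packages; it keeps the
per-interval character of the estimate — every tile still gets its own
$\phi$ — while borrowing enough strength across tiles that the LRT is
calibrated (simulations at 3v3 and $\phi = 0.1$ give type-I error
$\approx 0.05$; the test suite verifies the [0.03, 0.07] window). The LRT
is computed with the dispersion held fixed under both hypotheses.

**Fixed vs variable dispersion.** `mode = "fixed"` shares one $\phi$ per
tile across the compared groups — an analysis that assumes equal
replicate scatter. `mode = "variable"` gives each group its own $\phi_g$,
estimated from that group's replicates alone, so that genuine
between-group differences in replicate variability are absorbed into the
dispersion rather than surfacing as spurious mean shifts. On data
simulated with strongly heterogeneous group dispersions and no true mean
differences, the variable mode calls no more tiles than the fixed mode
(tested); this mirrors the analytical situation in which apparent
differential enrichment disappears once unequal scatter is allowed for.

**Significance rule.** A tile or CpG changes when its BH-adjusted p-value
is below 0.05 *and* its |log2 fold change| exceeds 0.6; both cuts are
strict inequalities and configurable. Where the 500 bp and 1,000 bp
analyses both flag overlapping tiles, the 500 bp call is reported.

## From reads to counts

* **Fragment centers** approximate each sequenced fragment's midpoint by
  shifting the read's 5′ position by half the mean fragment length,
  downstream on `+` and upstream on `-` (rounded half-length; the
  orientation convention stores the rightmost aligned base for `-`
  reads).
* **Domain calling** is a deliberately simple Poisson sliding-window
  segmenter: windows (default 2,000 bp, step 500 bp) are scored by the
  upper-tail Poisson p-value of their center count against the
  genome-wide mean density, BH-adjusted, and significant windows are
  merged into maximal runs. It is a documented stand-in for specialised
  external segmentation tools, adequate for density domains on the
  simulated genomes used here; its defaults are configuration, not
  biology.
* **Merging and tiling.** Domains on the same chromosome merge when their
  gap is strictly less than 1 kb. Merged domains are cut from their start
  into full 500 bp (and 1,000 bp) tiles; trailing remainders are
  dropped, a choice made so that every counting unit has identical
  length.
* **Filtering.** A tile is retained when its raw count reaches the
  mark-specific threshold in at least one sample (H3K4me2: 50 per 500 bp
  tile, 100 per 1,000 bp; H3K27me3: 30 and 60), read as an inclusive
  `>=` so the printed threshold is the minimal retained count. With input
  controls, a tile must additionally exceed its input by at least 7 reads
  in at least one ChIP sample; input counts are scaled to the ChIP
  sample's library size first, which keeps the comparison fair when
  depths differ (the raw-count variant corresponds to equal depths, the
  default after downsampling).

## The methylation arm

Probes failing detection (detection p ≥ 0.05 in *any* sample — small
detection p means above background, following array convention) or carrying
a blocklist flag (known polymorphism, multi-mapping, sex chromosome) are
removed. Normalization is dasen-style: per sample, type I intensities are
shifted additively so their 5th percentile matches the type II 5th
percentile of the same channel (an explicit, testable approximation to the
design-bias correction of the original scheme, whose exact smoothing is
not re-implemented here), then quantile normalization across samples is
applied separately within each channel × probe-type stratum, with ties
receiving the mean of the reference quantiles they span. Both
postconditions — exactly identical sorted stratum vectors across samples,
and idempotence on re-application — are asserted in the test suite.

M-values are $\log_2((\text{meth}+\alpha)/(\text{unmeth}+\alpha))$ with
$\alpha = 1$ by default; background-adjusted intensities may dip below
zero and are floored at 0 first. Group comparisons use a moderated t:
per-probe pooled variances $s^2$ (df $d$) are shrunk toward a prior
$s_0^2$ with prior df $d_0$,

$$\tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d},\qquad
  \tilde t = \frac{\Delta M}{\tilde s\sqrt{1/n_1 + 1/n_2}},$$

with p-values on $d + d_0$ df. $(d_0, s_0^2)$ come from closed-form
moment matching of a scaled-F distribution to the observed $s^2$ (if the
$s^2$ scatter no more than a single $\chi^2_d$ would, $d_0 = \infty$).
Forcing $d_0 = 0$ reproduces the ordinary pooled t exactly and
$d_0 = \infty$ a z-like statistic; both limits are tested, and the
estimates track the reference empirical-Bayes implementation closely on
random fixtures (rank correlation of p-values > 0.999).

One caveat the tests surface deliberately: quantile normalization couples
samples weakly, so on null data the moderated-t p-values after dasen are
calibrated at the 0.05 level but detectably non-uniform for a KS test at
5,000 probes; the uniformity check in the suite therefore runs on
un-normalized null M-values, the calibration check on the full pipeline.

## Replicate variability

For each tile and condition, CV² = (sd/mean)² of the CPM values across
that condition's replicates (sample sd, divisor $n-1$ — stated because
with two replicates the divisor scales every CV²). Tiles with zero
replicate mean have no defined CV² and are excluded, with the exclusion
count reported. For probes, the statistic is the unbiased variance of
M-values. Under the NB model the expected CV² is $1/\mu + \phi$, which
gives the module its quantitative anchor: at $\phi = 0.05$ and
lognormal $\mu$ (median 200), the mean CV² over 10,000 tiles lands within
a few percent of $\text{mean}(1/\mu) + \phi$ (tested at ±10%).

Conditions are compared by two-sided Wilcoxon rank-sum tests — exact by
enumeration when both sides have ≤ 10 observations and no ties, otherwise
the tie-corrected normal approximation with continuity correction —
globally and within strata (feature class, bivalency, dynamics class,
distance bins). Strata too small to test are reported with `p = NA`
rather than dropped, so the stratum accounting always partitions the tile
universe. Per-condition dispersion is the generator's knob for replicate
variability, so an induced dispersion drop in one condition must be (and
is, in the acceptance tests) recovered as a lower median CV² with
vanishing p globally, *and only in the targeted stratum* when the drop is
confined to, say, non-bivalent tiles — emulating analyses in which
bivalent chromatin is exempt from a variability effect.

## Genomic context

Feature assignment uses the tile midpoint with fixed precedence promoter >
exon > intron > intergenic, so labels always partition the tile set; the
overlap rule is a package decision since midpoints make the partition
property trivial to guarantee. Promoters are ±1,000 bp around the TSS,
strand-aware and clipped at chromosome bounds. Bivalent tiles are the
exact intersection of the filtered (post-threshold) 500 bp tile sets of
H3K4me2 and H3K27me3, computed on the pooled sample set of the analysis —
defining bivalency per condition instead is possible by filtering
per-condition subsets, but the pooled definition is the default because
the filter itself is defined across all samples.

## What the simulators emulate — and what they do not

* `simulateCounts()` draws NB counts per condition with lognormal tile
  abundances (`muLogMean = log(200)`, `muLogSd = 0.5` — tile sums well
  above the retention thresholds, as post-filter tiles are), spikes a
  fraction of tiles by a true fold change in the last condition, flags a
  bivalent subset, and lays tiles on a single toy chromosome `chrS`
  annotated by `simulateAnnotation()`. Per-condition dispersion (optionally
  overridden within the bivalent stratum) encodes robustness effects. It
  does *not* simulate read-level artefacts: no GC or mappability bias, no
  positional autocorrelation between neighbouring tiles, no
  condition-specific library-size structure.
* `simulateFragments()` plants Poisson background plus uniformly enriched
  domains and emits stranded read starts that invert exactly under
  `fragmentCenters()`. Real ChIP fragments have length variation and
  peaked (non-uniform) within-domain densities; the caller's recovery
  numbers on this fixture are therefore upper bounds on real-data
  behaviour.
* `simulateMethylation()` draws true methylation from a Beta mixture,
  adds replicate noise *on the M scale* (default sd 0.4, per-condition
  values allowed), shifts hyper/hypo probes by ±1.5 M units in the
  effect condition(s), splits a lognormal total intensity between
  channels and offsets type I probes additively — the design bias dasen
  removes. Real arrays have probe-specific affinities and spatial
  artefacts that are not modeled.

Consequently, passing tests demonstrate the statistical machinery is
correct and calibrated under the stated models; they do not certify
performance under real-data artefacts that the generators exclude.

## Numerical choices

* Dispersion grid: 40 log-spaced points on $[10^{-4}, 20]$ with quadratic
  interpolation of the optimum; estimates at the lowest grid point are
  reported as 0 (Poisson). Mean coefficients by Fisher scoring on
  $\log\beta$, tolerance $10^{-10}$, vectorized across tiles.
* LRT floored at 0 (numerical noise can make $\ell_1$ infinitesimally
  smaller than $\ell_0$); all-zero tiles are flagged `NA` and excluded
  from the BH denominator.
* Fold changes of zero-mean groups use a 0.5-count continuity offset on
  the CPM scale, applied to both groups, never to the likelihood.
* Quantile-normalization ties take the mean of the spanned reference
  quantiles; the 5th percentile uses the default interpolation of
  `quantile()`.
* Wilcoxon switches from exact to approximate above 10 observations per
  side or in the presence of ties; the two branches agree within 0.02 at
  the switch point (tested).

## Problem sizes

The test suite and the acceptance script use 5,000–10,000 tiles or probes
with 2–3 replicates per condition, and demo pipelines run a 1 Mb toy
genome with ~25 domains per mark at ~12 reads/kb background — sizes chosen
so the full suite exercises every stage, including two complete pipeline
re-runs for checksum determinism, in a couple of minutes on one CPU while
leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Single-factor, two-group comparisons only; no quasi-likelihood F-test,
  no trended dispersion, no multi-factor designs.
* CPM normalization with recorded library sizes; no TMM-style
  composition correction (inputs are depth-matched by downsampling
  upstream).
* The domain segmenter is a stand-in; boundary placement is
  window-quantized (±step) by construction.
* The dasen background step is a 5th-percentile alignment, not the
  original smoothed background correction; equivalence to the reference
  implementation is not claimed, calibration is tested instead.
* No claim of reproducing any real-data result: the package's numbers are
  properties of the stated simulation conditions.

## A short worked example

```{r example, eval = FALSE}
sim <- simulateCounts(nTiles = 2000, nReplicates = 2,
                      phiByCondition = c(sham = 0.15, ELF = 0.05),
                      seed = 1)
cpm <- normalizeCPM(sim$counts)
grp <- colData(sim$counts)$condition
cmp <- compareVariability(cv2(cpm, grp, "ELF"), cv2(cpm, grp, "sham"))
cmp
```

The median CV² of the low-dispersion condition sits near
$\text{median}(1/\mu) + 0.05$, the high-dispersion one near
$\text{median}(1/\mu) + 0.15$, and the Wilcoxon p-value is vanishingly
small — the robustness effect the package exists to measure.
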