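---
title: "Methods: ecogeographic and genetic structure of a range-edge plant population"
author: "vitisedge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecogeographic and genetic structure of a range-edge plant population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vitisedge` implements, as one tested pipeline, the family of analyses
used to characterize a plant population at the edge of its distribution
range: multivariate spatial clustering of ecogeographic variables,
microsatellite (SSR) population genetics, Bayesian admixture
clustering, maximum-entropy niche modeling, and the concordance and
phenotype statistics that tie those views together. The motivating
system is wild grapevine (*Vitis vinifera* ssp. *sylvestris*) at the
southern edge of its range, where a collection of about 130 accessions
splits into two ecogeographically and genetically distinct populations
joined by limited gene flow. This vignette explains each model, its
assumptions, the tunable parameters, and what the synthetic-data
generator does and does not emulate.

## The synthetic scenario and its ground truth

Every analysis stage can be exercised on data from `sim_config()` /
`gen_landscape()` / `gen_accessions()` / `gen_ssr_genotypes()` /
`gen_morphology()`, which carry a known ground truth:

* **Landscape.** A square grid in projected planar meters (default
  150 × 150 cells at 30 m, i.e. a 4.5 km domain; all distances are
  Euclidean, no geodesy). Seven continuous layers (slope, aspect,
  distance to water, spring and summer NDVI, land-surface temperature,
  precipitation) and three categorical layers (soil, lithology, land
  cover) are built from Gaussian-smoothed white noise (smoothing range
  10 cells by default, which is what makes the fields spatially
  autocorrelated), plus deterministic couplings: distance-to-water is
  the exact Euclidean distance transform of two meandering stream
  rasters, summer NDVI declines with that distance, and LST is
  negatively coupled to summer NDVI. The regional contrast —
  precipitation (350–410 mm, the range relevant for the species'
  water-limited southern edge), LST, and spring NDVI — changes as a
  smoothed step across the middle of the domain rather than a linear
  ramp: the study system consists of two ecogeographically *distinct*
  subareas, not a continuum. Each subarea carries its own stream
  system, leaving a drier gap at the interface, again mirroring the
  geography (two river basins with few intermediate sites).
* **Accessions.** 119 georeferenced accessions (plus 10 sampled but
  not georeferenced, emulating a 129/119 sampled/located split) drawn
  with occupancy weight `exp(eta)`, where `eta` is the true linear
  predictor on min–max-scaled layers (default coefficients −4 on
  distance to water, +2 on summer NDVI, +1 on precipitation).
  `exp(eta)` is the exponential family the maximum-entropy model fits,
  which is what makes the true coefficients recoverable; the logistic
  surface `plogis(eta)` is the corresponding probability-of-presence
  map. True populations are vertical geographic bands; ancestry decays
  linearly across a 600 m boundary band, giving genuinely admixed
  ground truth near the interface.
* **Genotypes.** 20 diploid SSR loci with 8 ancestral alleles each,
  under the Balding–Nichols drift model: population allele frequencies
  are Dirichlet draws with parameters `p (1 − F)/F`, so the drift
  parameter *F* is the target FST (default 0.2 — the spec of the
  scaled-down model-choice experiments; the real study's 0.038 would
  not be separable at this sample size and is not a useful test
  condition). Allele states become fragment sizes `150 + state ×
  repeat` bp. Null alleles silence individual allele copies (a
  heterozygote with one silenced copy looks homozygous; a doubly
  silenced genotype is missing), and missing genotypes are coded 0
  (GenAlEx convention) or −9 (STRUCTURE files).
* **Morphology.** 20 ordinal OIV-style descriptors on a 1–9 scale with
  a +2 shift for population 1 on the four hairiness descriptors, and a
  correlation structure of two trait blocks (hairiness, leaf shape)
  plus a weak general factor — related ampelographic traits co-vary on
  real plants, and this is what gives the trait PCA a realistic
  leading-axes share.

What the generator does **not** emulate: real satellite imagery and
its processing chain, geographic reprojection, linkage between loci,
genotyping error other than null alleles/missingness, and observer
effects in ordinal scoring. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the statistics, not the
field behavior of any particular data set.

## Multivariate spatial clustering

Environmental values are extracted at accession locations by the
nearest-cell rule. For each variable the Getis–Ord Gi\* statistic is
computed with binary distance-band weights (self included):

$$G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
  {S \sqrt{\left(n S_{1i} - W_i^2\right)/(n-1)}}$$

The Z-scores feed fuzzy c-means (FCM) with Euclidean distances,
fuzzifier *m* = 2 (the standard default; the method literature rarely
reports another value), tolerance 10⁻⁸ on the maximum centroid shift,
and 20 random restarts keeping the lowest objective; initial centroids
are distinct data rows. Points coincident with a centroid get
membership 1. Degenerate Gi\* denominators (a constant variable, or a
radius covering every point) are defined as Z = 0 — "no local signal"
rather than an error. The Gi\* p-value (two-sided standard-normal
tail) is reported but not used downstream. Cluster separation is
scored by the mean silhouette; hard labels are argmax memberships with
ties to the lowest cluster index. `select_clusters()` reports the
silhouette per candidate C and accepts either the silhouette optimum
or an externally imposed C — the study's own rule sets C from the
genetic clustering and uses the silhouette only as validation, and the
pipeline's concordance stage does the same whenever the silhouette
choice differs from the genetic K. Gi\* Z-scores are already
standardized by construction and are fed to FCM directly; an optional
re-standardization is available in `fcm()` inputs simply by scaling
the matrix first.

The default Gi\* radius is 5,000 m (`pipeline_config()`), appropriate
to a ~50 km study area; the bundled 4.5 km scenario uses 800 m
(`desk_config()`), about one sixth of the domain and twice the
field-autocorrelation range, so that neighborhoods pool regional
rather than local variation.

## SSR population genetics

Per population and locus: N, Na, effective alleles `Ne = 1/Σp²`, Ho,
`He = 1 − Σp²`, unbiased `uHe = 2N/(2N−1) He`, and the fixation index
`F = (He − Ho)/He` (undefined at He = 0). The Hardy–Weinberg
chi-squared test compares observed genotype counts with expectations
from observed allele frequencies on `k(k−1)/2` degrees of freedom;
classes with expected count below 1 are pooled into one residual class
so the statistic stays valid with many rare SSR alleles (the exact
Guo–Thompson test is out of scope). Null-allele frequencies are
reported with both the Chakraborty (`(He−Ho)/(He+Ho)`) and
Brookfield-1 (`(He−Ho)/(1+He)`) estimators, since heterozygote-deficit
summaries do not identify which one any given report used. Private
alleles are counted as alleles observed in exactly one population,
summed over loci.

**AMOVA and FST.** Molecular variance is partitioned among and within
groups at the *gene-copy* level: the package enumerates, per locus,
all ordered pairs of the 2N allele copies through per-pair
cross-mismatch counts (which makes the computation independent of
phase), skips loci missing in either member of a pair with per-pair
renormalization, and derives variance components from the standard
mean-square equations. The resulting Φ-statistic is reported as FST.
This is the codominant route of the GenAlEx tradition and is unbiased
for the drift parameter; a two-level AMOVA on whole-genotype distances
would instead estimate 2F/(1+F) and was rejected for that reason. A
multi-allele Weir–Cockerham θ is included as an independent
cross-check. Permutation significance shuffles whole individuals
across groups with the +1/+1 correction, so p is never zero; pairwise
FST between group pairs uses the same machinery, and gene flow is the
island-model `Nm = (1 − FST)/(4 FST)`.

**Distances, trees, ordination.** Bruvo distance uses
`1 − 2^(−|Δsize|/repeat)` per allele pair and the exact minimum over
the two diploid matchings (no genome addition/loss models — all data
are diploid); individual distances average pairwise-complete loci.
Neighbor joining is delegated to `ape::nj()`; bootstrap support
resamples *loci* (the standard unit for multilocus trees) and counts
bipartitions over replicates; an outgroup roots the reported tree.
PCoA is the Gower double-centering of −d²/2 with eigenvector
coordinates scaled by the square roots of the positive eigenvalues;
negative eigenvalues are dropped from the percent-variance denominator
with a warning. The simple allele-mismatch genotype distance
(`genotype_sqdist()`) is available as the alternative ordination
metric.

## Bayesian admixture clustering and ΔK

`structure_gibbs()` is a Gibbs sampler for the admixture model with
*independent* Dirichlet(λ = 1) cluster allele frequencies: allele-copy
origins are sampled proportional to `q_ik p_k(a)`, ancestry rows from
Dirichlet(α + origin counts) with α fixed at 1, and cluster
frequencies from Dirichlet(λ + allele counts); missing alleles are
skipped. The correlated-allele-frequency (F-model) prior is a
documented out-of-scope deviation; on moderately-to-strongly diverged
data, where the package's model-choice and recovery tests operate, the
two priors agree. Reported Q and P are posterior means over the kept
sweeps; the model evidence is summarized by the classic
`lnPD = mean(lnL) − var(lnL)/2`. The sampler is written in C++ for
throughput and uses R's RNG, so runs are exactly reproducible under a
seed. Label switching across replicate runs is resolved by greedy
column matching of Q to the first run (maximizing column
correlations), replacing external post-processing tools.

ΔK follows the Evanno construction,
`ΔK = |mean lnPD(K+1) − 2 mean lnPD(K) + mean lnPD(K−1)| / sd lnPD(K)`,
computed from per-K means and standard deviations over runs (the
convention of the widely used implementations); interior K with zero
spread are flagged rather than divided by zero. Paper-scale settings
(K = 1..9, 20 runs, 5,000 burn-in, 50,000 kept sweeps) are the
`pipeline_config()` defaults; tests and the bundled scenario use
desk-scale chains (200/600–800), which the fixed-allele and
doubling-invariance tests show are long enough for the data sizes
involved.

## Maximum-entropy niche model

Features are linear and quadratic transforms of min–max-scaled
continuous variables (scaling constants from the background only) and
one indicator per observed categorical level; hinge/product/threshold
features are a documented omission, and all smooth-truth tests are
designed around that restricted set. The fit maximizes the
L1-penalized presence log-likelihood of the background-normalized
Gibbs distribution by proximal-gradient ascent with backtracking — a
convex problem, so the optimum is unique and order-invariant; the
default penalty is β = 0.05 per feature on the [0, 1] feature scale.
The logistic output is `r e^H / (1 + r e^H)` with `r` the raw
(background-normalized) output and `H` the entropy of the fitted
background distribution. Evaluation repeats random 75/25
train/test splits (rounding toward training) and scores the rank
(Mann–Whitney) AUC against the background, ties counting one half —
with background pseudo-absences an AUC of 1 is not attainable in
realistic settings, and the bundled scenario sits near 0.75 rather
than the >0.9 of sharply water-limited real data. Variable importance
is permutation importance (drop in training AUC, floored at zero,
normalized to 100); the path-dependent "percent contribution"
heuristic of the original software is deliberately not reproduced. The
collinearity pre-screen reports the background correlation matrix and
leaves exclusions to the analyst, since no universal threshold exists.

## Concordance and phenotype statistics

Two binary partitions of the same accessions are compared by aligning
labels to maximize agreement and applying McNemar's test to the
discordant cells, `(|b−c|−1)²/(b+c)` with continuity correction by
default (both corrected and uncorrected values are always reported);
`b + c = 0` is reported as undefined rather than significant.
Morphology is summarized by PCA of centered, unit-variance ordinal
codes — a deliberate simplification of optimal-scaling (PRINCALS)
categorical PCA, with loadings interpreted only ordinally — and by
two-sample Wilcoxon–Mann–Whitney rank-sum tests with mid-ranks and the
tie-corrected normal approximation. A paired signed-rank test is not
applicable to two independent groups of unequal size, which is why the
rank-sum form is used throughout.

## Pipeline, seeds, and problem sizes

`run_pipeline()` executes simulate → extract → spatial-cluster →
popgen → structure → sdm → concordance → phenotype, writing every
output in plain-text exchange formats (ESRI ASCII grids, GenAlEx and
STRUCTURE genotype files, samples-with-data CSV, Newick) plus a
manifest per stage (file hashes, seed, runtime). All stage seeds
derive deterministically from one master seed, so reruns are
byte-identical. The package's interface is its R functions — the
pipeline is driven from R or small Rscript wrappers such as
`scripts/acceptance.R`; no separate shell tool is shipped.

Problem sizes used by the test suite were chosen to exercise every
code path at desk scale: landscapes of 40–150 squared cells, 60–129
accessions, 16–200 individuals per genetic test, Gibbs chains of
300–4,000 kept sweeps, 10-seed replications for stochastic
regime checks, and 200-replicate uniformity checks for the permutation
and rank tests. The known limitations worth restating: the FCM
silhouette can legitimately prefer a finer C than the regional truth
when local environmental structure is strong (two of eight scenario
seeds do this; the concordance stage then imposes the genetic K, as
the study itself did); the lnPD evidence summary is a second-order
approximation whose error grows with data size (its analytic check
therefore runs on a small panel); and Bruvo distance is not guaranteed
metric, so triangle-inequality violations are tallied, not asserted.
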