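# vitisedge

Population structure of a plant species at the edge of its range,
analyzed end to end: **ecogeographic spatial clustering**, **SSR
population genetics**, **Bayesian admixture clustering**, a
**maximum-entropy niche model**, and the **concordance and phenotype
statistics** that connect them. The package is modeled on studies of
wild grapevine (*Vitis vinifera* ssp. *sylvestris*) at the southern
edge of its distribution, where ~130 accessions split into two
ecogeographically and genetically distinct populations connected by
limited gene flow. It is written for population geneticists and
ecologists who want the whole analysis chain as tested, scriptable R
functions, exercised against synthetic data with known ground truth.

## What it computes

* **Spatial clustering** (`gi_star`, `fcm`, `silhouette_index`,
  `select_clusters`): per-variable Getis-Ord Gi\* hot-spot Z-scores
  with binary distance-band weights,
  `Gi* = (Σ w_ij x_j − X̄ W_i) / (S √[(n S1_i − W_i²)/(n−1)])`,
  fuzzy c-means (fuzzifier m = 2, 20 restarts) on the Z-score matrix,
  and silhouette validation of the hard partition.
* **SSR population genetics** (`diversity_stats`, `hwe_test`,
  `private_alleles`, `null_allele_freq`, `amova_fst`, `wc_fst`,
  `bruvo_distance`, `nj_tree`, `pcoa`): Na/Ne/Ho/He/uHe/F per locus
  and population; chi-squared HWE tests with pooling of rare classes;
  Chakraborty and Brookfield-1 null-allele estimators; gene-copy-level
  AMOVA whose Phi-statistic is reported as FST with permutation
  significance, pairwise FST and island-model `Nm = (1−FST)/(4·FST)`;
  Bruvo distances (`1 − 2^(−Δ/repeat)`, exact diploid matching);
  neighbor-joining trees with locus-bootstrap support; principal
  coordinates.
* **Admixture clustering** (`structure_gibbs`, `align_labels`,
  `delta_k`): a C++ Gibbs sampler for the admixture model with
  independent Dirichlet allele-frequency priors, posterior-mean Q/P,
  `lnPD = mean(lnL) − var(lnL)/2`, greedy label alignment across
  runs, and Evanno ΔK model choice.
* **Niche model** (`fit_maxent`, `logistic_output`,
  `replicate_evaluate`, `permutation_importance`, `predict_map`,
  `response_curves`): L1-penalized maximum-entropy fit over
  linear/quadratic/categorical features by convex proximal-gradient
  ascent, logistic suitability output, replicate 75/25 AUC
  evaluation, permutation variable importance, suitability rasters and
  response curves.
* **Concordance and phenotype** (`crosstab_aligned`, `mcnemar_chi2`,
  `morph_pca`, `rank_test`): label-aligned McNemar comparison of the
  genetic and ecogeographic partitions, PCA of standardized ordinal
  trait codes, and tie-corrected rank-sum tests per descriptor.
* **Synthetic data** (`sim_config`, `gen_landscape`, `gen_accessions`,
  `gen_ssr_genotypes`, `gen_morphology`): landscapes as ESRI ASCII
  grids, accessions with admixed ground-truth ancestry, diploid SSR
  genotypes under a Balding-Nichols drift model at a target FST, and
  ordinal morphology with group effects; everything deterministic
  under a seed.

File formats: ESRI ASCII grid (`read_asc`/`write_asc`), GenAlEx-style
and STRUCTURE genotype files (`read_genotypes`, `write_genalex`,
`write_structure`), Maxent samples-with-data CSV, morphology CSV,
Newick trees.

## Worked example

```r
library(vitisedge)

config <- desk_config(seed = 1)          # bundled synthetic scenario
state  <- run_pipeline(config, outdir = "out")

state$spatial$C                          # 2
round(state$spatial$silhouette, 2)       # 0.54
state$K_selected                         # 2
round(state$amova$phi_st, 3)             # 0.235
round(state$amova$table$percent[1:2], 1) # 23.5 76.5
state$amova$p                            # 0.005
state$mcnemar$chi2; state$mcnemar$p      # 0, 1
round(sort(state$sdm_importance, decreasing = TRUE)[1:2])
# dist_water       soil
#         75         10
```

Reading: the fuzzy ecogeographic clustering picks C = 2 regions
(silhouette 0.54) and the Evanno ΔK picks K = 2 genetic clusters —
both equal to the simulated truth; the AMOVA attributes 23.5% of
molecular variance to the between-cluster level (FST 0.235 against a
drift target of 0.2, p = 0.005 with 199 permutations); McNemar finds
no disagreement between the genetic and ecogeographic partitions
(χ² = 0 on one discordant accession, p = 1); and the niche model ranks
distance to water as the dominant environmental constraint, the
planted truth.
`out/` holds every table, raster and tree in plain-text formats plus
a manifest per stage.

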