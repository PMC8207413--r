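Package: vitisedge
Title: Ecogeographic Clustering, SSR Population Genetics and Niche
    Modeling for Range-Edge Plant Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested pipeline for analysing the population
    structure of a plant species at the edge of its distribution range,
    modelled on studies of wild grapevine (Vitis vinifera ssp.
    sylvestris) in the southern Levant. Combines multivariate spatial
    clustering of ecogeographic variables (Getis-Ord Gi* hot-spot
    statistics followed by fuzzy c-means with silhouette validation),
    microsatellite (SSR) population genetics (heterozygosity and
    fixation statistics, Hardy-Weinberg and null-allele tests, private
    alleles, AMOVA-based FST and gene flow, Bruvo distance,
    neighbor-joining trees with locus bootstrap, principal coordinates),
    Bayesian admixture clustering with Evanno delta-K model choice, a
    maximum-entropy species distribution model with replicate AUC
    evaluation and permutation variable importance, and
    concordance/phenotype statistics (McNemar's test, ordinal-trait PCA,
    rank-sum tests). A synthetic-data module generates landscapes,
    accessions, genotypes and morphology with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
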