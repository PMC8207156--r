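Package: latdiv
Title: Population Divergence Analysis Along Latitudinal Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the divergence of parapatric plant lineages
    distributed along a latitudinal environmental gradient, built around
    diploid biallelic SNP genotype matrices. Provides genotype filtering
    (call rate, minor allele frequency, Hardy-Weinberg equilibrium),
    per-population diversity statistics, per-locus Fst, hierarchical AMOVA
    and pairwise Phi distances with permutation tests, an Fst-heterozygosity
    confidence-envelope outlier scan, a Phi(outlier)/Phi(neutral) selection
    regime ratio scan over nested population groups, coalescent SNP
    simulation under four divergence/admixture scenarios with approximate
    Bayesian computation for scenario choice and parameter estimation,
    distance-matrix regression models ranked by AICc with Mantel tests,
    and ecological niche breadth/overlap statistics with a background
    similarity test. A synthetic-data generator emulates the gradient
    structure of ddRAD-seq SNP studies so the full pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
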