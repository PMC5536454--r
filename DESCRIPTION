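Package: pottsevo
Title: Cellular Potts Simulation of Tumor Micro-Evolution Under Fluctuating
    Vascular Nutrient Supply
Version: 0.1.0
Authors@R:
    person("Potts", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional cellular Potts model of a confluent, mutating
    epithelial cell population metabolizing glucose and oxygen supplied by
    stochastically blocking vessel cross-sections. Cells carry ten heritable
    phenotype parameters (compressibility, division volume, adhesion-molecule
    densities, chemotaxis coefficients, growth signal, and metabolic switch
    thresholds) that mutate at division as a reflected Gaussian random walk.
    Metabolism mixes lactic-acid fermentation and respiration under control of
    a hypoxia factor with a reactive-oxygen-species feedback, reproducing a
    Warburg-type metabolic lock-in. The package provides the lattice engine
    (Metropolis copy dynamics), reaction-diffusion nutrient fields, vessel
    blocking schedules, cell lifecycle and evolution rules, experiment
    presets, and a phenotype-space analysis toolkit (principal axes and
    Ward-linkage clustering of mutational displacement).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
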