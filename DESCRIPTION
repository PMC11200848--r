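Package: mcomeda
Title: Multiscale Complexity Analysis of Electrodermal Activity
Version: 0.1.0
Authors@R: person("mcomeda", "developers", role = c("aut", "cre"),
    email = "mcomeda@example.org")
Description: Phase-space complexity analysis of skin-conductance (electrodermal
    activity, EDA) recordings. Implements the ComEDA index -- quadratic Renyi
    entropy of the distribution of angular distances between Takens-embedded
    phase-space vectors, estimated with a diffusion kernel density estimator
    and Sturges binning -- and its multiscale extension MComEDA, the area under
    the ComEDA-versus-scale curve obtained by coarse-graining the signal.
    Includes EDA pre-processing (anti-aliased downsampling, tonic/phasic
    decomposition, z-scoring), embedding-parameter selection via auto mutual
    information and false nearest neighbours, the EDASymp spectral sympathetic
    index, a paired nonparametric group-comparison workflow (Lilliefors,
    Friedman, Wilcoxon signed-rank with Bonferroni correction), and a seeded
    generator of EDA-like synthetic signals and cohorts for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
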