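Package: slowfast
Title: Adaptive Divergence of Slow-Fast and Leaf-Economics Trait Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qst-Fst style analysis of trait-syndrome divergence among lineages
    of predominantly selfing plants. Provides Weir-Cockerham Fst estimation from
    haploid-coded SNP genotypes with permutation-based per-SNP significance and
    an intergenic neutral-Fst benchmark, Pst estimation adapted to autogamous
    species with c/h2 sensitivity analysis, critical-ratio computation and
    parametric-bootstrap confidence intervals, leaf-economics-spectrum and
    slow-fast trait axes via correlation-matrix PCA, logistic growth-curve
    fitting with relative-growth-rate extraction, standardized major axis
    regression for leaf-to-plant trait scaling, kinship-aware generalized least
    squares, and climate-trait association with stepwise model selection and
    repeated cross-validation. Includes seeded simulators (island-model
    genotypes, variance-structured phenotypes, logistic growth series, coupled
    climate tables) that emulate the statistical structure the analysis
    assumes, so the whole pipeline can be exercised and calibrated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
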