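Package: cazynet
Title: Co-Occurrence Network Analysis of Microbial Carbohydrate-Active Enzyme Gene Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares signed co-occurrence networks of microbial
    carbohydrate-active enzyme (CAZy) gene families from compositional
    metagenomic abundance tables. Implements SparCC basis-correlation
    inference with permutation significance and Benjamini-Hochberg
    correction, correlation-thresholded network construction, topology
    summaries (connectivity, path length, clustering, centralisation,
    fast-greedy modularity, power-law fit), Zi-Pi node-role classification,
    stability analysis (efficiency-based robustness under random and
    targeted attack, node vulnerability, per-sample cohesion), module
    eigengene-environment correlation, and a synthetic compositional data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    multcomp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
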