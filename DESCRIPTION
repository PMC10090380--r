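Package: phyloconcord
Title: Gene Tree-Species Tree Concordance with Information-Aware RF
    Normalization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies topological concordance between single-gene trees
    and a reference species tree using Robinson-Foulds (RF) distances,
    with a polytomy-based exclusion rule, gene-set summaries and relative
    RF statistics. Corrects for unequal phylogenetic information content
    across genes by fitting a quantile baseline of RF distance against
    log10 of the number of parsimony-informative sites and dividing each
    RF value by its fitted baseline. Also implements a clade-proportional
    random genome resampling design (largest-remainder apportionment of
    replicate slots across clades) with resampling and overlap
    diagnostics, and a fully synthetic data generator (Yule species
    trees, NNI-perturbed gene trees, Poisson-style protein alignment
    evolution) so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
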