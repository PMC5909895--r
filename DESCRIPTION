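Package: cofswap
Title: Constraint-Based Modeling of Cofactor Swapping in E. coli Acetate
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis of the metabolic consequences of changing
    the cofactor specificity of isocitrate dehydrogenase (NADP+ to NAD+) in
    Escherichia coli growing on acetate. Provides SBML/JSON model input and
    output, stoichiometric edits for fractional cofactor swapping, gene
    knockouts and reaction irreversibility, a linear-programming engine for
    FBA, flux variability, robustness and phenotype phase-plane analyses, an
    iterative optimization procedure that selects a unique optimal flux
    distribution via MILP enumeration of alternate optima, artificially
    centered hit-and-run sampling of sub-optimal flux space, and accounting
    of cofactor production, ATP allocation and the isocitrate branch-point
    partition. Ships hand-solvable synthetic networks so the entire workflow
    is testable without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
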