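Package: mutregion
Title: Mutation Region Detection for Closely Related Individuals Without a Pedigree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate disease-mutation regions from unphased SNP
    genotypes of closely related affected and unaffected individuals when the
    pedigree is unknown. Phases fixed-length windows under a parsimony model
    using Clark's inference rule so that every affected individual shares one
    center haplotype carried by no unaffected individual, scans a chromosome
    for such windows, merges, refines and extends them into reported regions,
    and ranks regions by a sharing score. Includes a gene-dropping pedigree
    simulator with chi-square crossover interference and founder-haplotype
    generation, plus precision/recall evaluation of reported regions against
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
VignetteBuilder: knitr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
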