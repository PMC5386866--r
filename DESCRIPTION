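Package: sibmap
Title: Multi-Pedigree Linkage Mapping and Composite Genetic Maps for
    Full-Sib Outcross Populations
Version: 1.0.0
Authors@R:
    person("Maintainer", "sibmap", email = "sibmap@example.org",
           role = c("aut", "cre"))
Description: Tools for pseudo-testcross linkage mapping in full-sib
    families of outcrossing species: two-point recombination estimation
    and LOD grouping, minimum-spanning-tree seriation with local-search
    ordering, Kosambi distances by weighted regression, iterative
    nearest-neighbour cleaning, linkage-informed phasing and imputation,
    splitting of biparental markers, genotyping-error detection and bin
    mapping, linear-programming consensus (composite) map construction
    with RMSE-based interval selection, segregation-distortion scans and
    distortion-region calling, centromere localisation from bidirectional
    phased recombination-frequency profiles, maternal versus paternal
    recombination comparisons, pedigree coancestry, and a truth-annotated
    meiosis and pollen-tetrad simulator so the whole pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
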