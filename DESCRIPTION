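Package: sdmap
Title: Single-Dose Marker Linkage Mapping and Chromosome Pairing Analysis
    for Autopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetic mapping of dominant single-dose (presence/absence)
    markers in a polyploid pseudo-testcross. Classifies marker dosage from
    segregation ratios at arbitrary even ploidy, estimates two-point
    recombination fractions and LOD scores, forms and orders linkage groups
    with Haldane map distances, assembles linkage groups into homology
    groups from multi-allelic anchor loci, and detects preferential
    chromosome pairing through repulsion-phase linkage and a normalised
    interval difference ratio. Includes a forward simulator of polysomic and
    preferential-pairing meiosis that generates marker matrices with known
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
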