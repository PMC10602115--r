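Package: iwgorigin
Title: Founder Inference for Improved Intermediate Wheatgrass Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Traces modern food-grade intermediate wheatgrass (Kernza)
    germplasm back to its founder plant-introduction (PI) accessions.
    Implements depth-gated genotype calling from genotyping-by-sequencing
    (GBS) allele depths, marker and genet filtering, composite accession
    profiles, distance-based population assignment with leave-one-out
    masking validation, founder counting under germplasm-availability
    constraints, cross-source intersection summaries, passport-data
    geographic summaries, and reconstruction of a historical polycross
    parent selection from phenotype records. A synthetic polycross/GBS
    data generator (Balding-Nichols accession divergence, Mendelian
    polycross descent, Poisson read depth) makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
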