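Package: scaffotyper
Title: 3D Comparative Scaffotyping of Chromosome-Scale Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies orthologous chromosome-scale scaffolds across related
    species by combining homologous synteny blocks derived from pairwise
    whole-genome alignments, classification of chromosome rearrangements
    (inversions, fusions, fissions, translocations), and comparison of Hi-C
    A/B-compartment eigenvectors lifted onto a common reference. Includes
    tools to chain alignment blocks into synteny blocks at a configurable
    resolution, compute compartment eigenvectors from raw contact matrices
    (matrix balancing, distance normalisation, Pearson correlation, leading
    principal component), call cross-species compartment shifts, assemble and
    name cross-species orthology tables, and simulate genomes with scripted
    rearrangement histories and Hi-C counts with planted compartments for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
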