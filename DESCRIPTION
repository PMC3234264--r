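Package: irilmap
Title: Linkage Maps from Intermated Recombinant Inbred Lines and
    Genome-Assembly Colinearity Checks
Version: 0.1.0
Authors@R:
    person("Map", "Pipelines", email = "maps@example.org", role = c("aut", "cre"))
Description: Simulation, quality control, and de-novo construction of
    high-density genetic linkage maps from intermated recombinant inbred
    line (IRIL) populations genotyped on SNP arrays. Implements
    intensity-cluster pattern classification and genotype calling,
    marker-level quality statistics (failure rates, pedigree triplets,
    duplicate concordance, segregation-distortion scans, Dice similarity
    dendrograms), prioritized SNP panel selection, a scaffold to
    framework to bin-placement mapping strategy with
    intermating-corrected centiMorgan distances, and systematic
    comparison of genetic maps against a physical genome assembly
    (non-syntenic markers, non-colinear regions, Marey-map recombination
    landscapes, predicted physical positions, polymorphism deserts).
    A synthetic-data module generates IRIL populations, noisy array
    genotypes, two-channel intensity clusters, and corrupted assemblies
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
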