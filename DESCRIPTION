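Package: epigbsr
Title: Reference-Free epiGBS: Simulation, Preprocessing, and Bisulfite
    Fragment Reconstruction
Version: 0.1.0
Authors@R:
    person("epigbsr", "developers", email = "epigbsr@example.org",
           role = c("aut", "cre"))
Description: Tools for single-enzyme epi-genotyping-by-sequencing (epiGBS)
    libraries without a reference genome. Provides a forward simulator of
    bisulfite-converted GBS read pairs with ground truth, in-silico
    restriction digestion, demultiplexing, restriction-overhang trimming,
    read joining, expected-error quality filtering, wobble-based PCR clone
    removal, bisulfite conversion-rate estimation from an adapter check
    cytosine, a simplified exact-match locus/catalog builder compatible
    with Stacks v2 catalog FASTA files, reconstruction of the original
    pre-bisulfite fragment sequences by purine/pyrimidine (RY)
    reverse-complement pairing of the two converted strands, mock genome
    assembly with a fragment boundary table, and mapping of mock-genome
    coordinates back to fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
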