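Package: genomelanes
Title: Comparative Multi-Genome Annotation Tracks with Homology Swim Lanes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless backend for comparative browsing of multiple
    annotated genomes. Maintains a catalog of gene models (GFF3) across
    strains and organisms under a canonical-gene abstraction, resolves
    cross-genome homology (strain instances, orthologs, inferred
    paralogs), computes reference-mapped, 5'-aligned and split comparative
    views with a serializable view state, extracts genomic, spliced
    transcript and CDS sequences through a capped sequence cart, builds
    and reads a chunked static-file data store, filters features by
    biotype, length, presence and gene lists, and renders deterministic
    SVG track images with orientation-colored swim-lane connectors. A
    seeded synthetic fixture generator produces complete multi-genome
    test worlds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
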