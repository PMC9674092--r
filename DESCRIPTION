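Package: mitoCilia
Title: Motile-Ciliogenesis Program Analysis for Stressed Astrocytes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and quantify activation of a motile-ciliogenesis
    gene-expression program in bulk differential-expression data, as seen in
    astrocytes with mitochondrial DNA depletion. Builds up/down-regulated gene
    lists under explicit threshold policies, scores curated gene catalogs
    (ciliary, astrogliosis, lipid) with hypergeometric over-representation
    tests, scans TSS-centered promoter windows with position weight matrices
    and tests central motif enrichment against a random-gene negative set,
    tests positional enrichment of transcription-factor ChIP-seq peaks near
    transcription start sites against resampled negative gene sets, and
    computes cilium morphometry (oriented-bounding-box length proxy,
    tortuosity, morphology classes) with distributional group comparisons.
    A seeded synthetic-data generator produces every input with planted,
    parameterized signal for ground-truth recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
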