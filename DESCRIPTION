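Package: memfluid
Title: Membrane Fluidity, Mosaic and Lipid Composition Analyses for C. elegans Glucose-Toxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify in vivo membrane fluidity and transgene mosaicism
    in Caenorhabditis elegans glucose-toxicity experiments. Implements a
    model-free FRAP (fluorescence recovery after photobleaching) pipeline with
    acquisition-bleaching correction, min-zero/pre-bleach normalization and
    non-parametric mobile-fraction and half-time estimation, plus an
    exponential-fit cross-check; Dollo-parsimony inference of extrachromosomal
    array loss events on the early embryonic lineage tree from graded tissue
    scoring matrices; phospholipid fatty-acid saturation summaries (mol% by
    carbon count and double bonds) with condition contrasts; Wald proportion
    intervals, Welch t-tests and codon-change annotation for small worm assays.
    Packaged fixtures encode the mutant-allele and mosaic-scoring tables the
    analyses were designed around, and seeded generators produce synthetic
    inputs with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
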