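Package: phylorphan
Title: Phylostratigraphy and Origin Mechanisms of Orphan Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes of a focal species as conserved, taxonomically
    restricted, or species-specific orphans by a three-step homology cascade,
    assigns phylostrata on a ladder-like species phylogeny, traces residual
    homology of species-specific orphans through annotated transcripts,
    genome, and transcriptome assemblies, validates gene structures from
    spliced RNA-seq alignments, diagnoses mechanisms of orphan origin
    (chimeric assembly, gene splitting, reading-frame shifts, strand
    switching, overprinting, homology-search failure, and de novo birth from
    non-coding sequence), and tests selection on candidate open reading
    frames with a codon substitution model. Ships a multi-species genome
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
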