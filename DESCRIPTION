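Package: circedit
Title: Integrated Analysis of A-to-I RNA Editing and Circular RNA Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline linking loss of adenosine-to-inosine
    (A-to-I) RNA editing in intronic Alu elements to circular RNA (circRNA)
    formation. Implements RNA editing site calling from pileups with known-SNP
    and matched-DNA exclusion, back-splice junction detection from
    non-linearly-mapped reads via terminal anchor alignment with GT-AG
    breakpoint resolution, overlap of editing events with introns flanking
    back-splice sites, Alu-pair orientation analysis in flanking introns,
    normality-gated group statistics, and quantification of A-to-I editing in
    Sanger clone sequences. Ships a synthetic-data generator that plants
    editing sites, heterozygous SNPs and back-splice junctions with a
    machine-readable truth manifest so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
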