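Package: smarmseq
Title: Low-Input rRNA 2'-O-Methylation Scoring and Single-Embryo Spike-In Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for low-input RiboMeth-seq style profiling of
    rRNA 2'-O-methylation from read 5'-end frequencies, together with the
    companion single-embryo RNA-seq computations: ERCC spike-in absolute
    quantification, intron-retention scoring with a contiguous-intronic-bases
    rule, expression-based genotype calling, and Mendelian chi-square tests.
    Includes synthetic-data generators with recorded truth (alkaline-hydrolysis
    fragment simulation, spiked embryo cohorts, toy alignments) so every
    estimator can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
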