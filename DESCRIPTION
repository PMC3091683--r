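Package: spliceortho
Title: Splicing Orthology of Exon-Intron Structures Between Orthologous Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects transcript gene models onto their coding exon-intron
    structures (coding exon lengths and intron phases), aligns structures of
    transcripts from orthologous gene pairs with a global dynamic-programming
    aligner aware of intron gain and loss, classifies best-scoring transcript
    pairs into three iso-orthology categories of decreasing stringency (ISO1,
    ISO2, ISO3) or "no match", and summarizes results per transcript, per
    gene pair and per cohort. Includes readers and writers for
    genePred/refFlat-style gene models and ortholog-pair tables, and a
    synthetic orthologous-gene generator that produces cohorts with labelled
    splicing divergence for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
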