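Package: refstab
Title: Reference Gene Screening and RT-qPCR Stability Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines multi-dataset RNA-seq FPKM matrices for candidate
    reference (housekeeping) genes through an abundance, ratio-window,
    ANOVA and cross-dataset presence cascade with correlation-based final
    selection, then ranks candidates measured by RT-qPCR with four
    stability algorithms (geNorm, NormFinder, BestKeeper, comparative
    delta-Ct) combined into a geometric-mean comprehensive rank.  Includes
    standard-curve amplification-efficiency estimation, relative
    expression quantification against single or combined reference genes,
    and a synthetic-data generator with planted ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
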