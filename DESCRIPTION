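Package: tfbscan
Title: Promoter Scanning for Transcription Factor Binding Sites and
    Differential Expression Set Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers candidate transcription factor targets from promoter
    sequence: extracts strand-aware upstream windows around transcription
    start sites, scans them for exact matches to IUPAC degenerate consensus
    patterns, flags promoters whose per-motif occurrence counts fall outside
    the genome-background mean plus or minus one standard deviation, and
    retains transcription factor-target pairs whose expression changes agree
    in direction. Also provides the surrounding differential-expression set
    algebra (threshold filtering, comparison overlaps, category up/down
    summaries, expression-signature concordance) and a synthetic-data
    generator that plants motif occurrences and expression effects so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    jsonlite,
    withr,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
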