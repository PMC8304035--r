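Package: asmsynergy
Title: Multi-Assembler De Novo Transcriptome Evaluation and Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates de novo transcriptome assemblies produced by multiple
    assemblers and quantifies assembler synergy. Provides adaptive k-mer
    scheduling for de Bruijn graph assemblers, consensus assembly
    construction (merge, length filter, greedy redundancy reduction),
    assembly quality metrics (completeness against a marker set,
    read-representation rate, N50/N90 contig statistics) with parsers for
    real BUSCO and aligner summaries, a baseline-anchored Average Assessment
    Score (AAS) normalized to [-0.5, +0.5], and exhaustive single-, bi- and
    tri-assembler combination ranking with paired t-tests under FDR
    correction. A synthetic-data generator makes every stage testable
    without external tools or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
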