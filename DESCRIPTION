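Package: lncfruit
Title: Identification and Characterization of Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("lncfruit", "developers", email = "lncfruit@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying long non-coding RNAs (lncRNAs)
    from assembled transcript models and characterizing them against a
    protein-coding reference. Provides positional classification of novel
    transcripts (intergenic, antisense, sense-overlapping, intronic), a
    five-stage artifact filter cascade (length, EST/ncRNA/protein homology,
    ORF-based coding potential, expression), transposable-element overlap and
    per-family Fisher enrichment with fixed-width window density tracks,
    Shannon-entropy tissue-specificity scoring, ripening-stage differential
    expression with Benjamini-Hochberg FDR and lincRNA-mRNA proximity pairing,
    and strand-oriented DNA-methylation metaprofiles around transcription
    start sites. A synthetic-data module generates toy genomes with planted
    ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
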