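Package: certl
Title: Cross-Study Consensus Transcript Lists and Promoter Motif
    Over-Representation for Endometrial Receptivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Research-synthesis toolkit for the transcriptome of the
    endometrial window of implantation. Harmonizes differential-expression
    gene lists from independent microarray studies onto canonical cluster
    identifiers, applies a direction-aware vote-counting filter to derive a
    consensus receptivity transcript list, tests gene-set over-representation
    with an exact hypergeometric statistic under false-discovery-rate control,
    and analyses promoter sequences for transcription-factor binding sites:
    position weight matrix construction, information-weighted
    matrix-similarity and log-odds scanning on both strands, and an ensemble
    of three motif over-representation statistics (gene-level hypergeometric,
    site-rate binomial, and label permutation) combined by a cross-method
    consensus rule. A synthetic-data module generates multi-study gene lists
    and Markov-background promoter sets with planted ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
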