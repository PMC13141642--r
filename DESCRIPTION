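Package: bescan
Title: Base-Editor Guide Design for Gene Disruption in Filamentous Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans genomes for CRISPR base-editor (CBE/ABE) guide sites under
    NGG or relaxed NG PAMs, enumerates deaminase edits within the protospacer
    editing window, classifies candidate edits into three gene-disruption
    strategies (premature stop-codon introduction, start-codon loss, and
    splice-signal disruption with predicted intron retention), and aggregates
    per-gene targetability into genome-wide summary tables. Includes a
    synthetic-genome simulator with planted, manifest-tracked target sites
    and an albA-like fixture gene for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
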