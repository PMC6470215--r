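Package: primerfusion
Title: Multi-Primer 16S rRNA Amplicon Profile Merging and Coverage Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines taxon abundance tables produced by several
    region-specific 16S rRNA primer sets into a single microbiome profile
    under the representative-throughput rule (unique taxa keep their read
    count, taxa shared between primer sets take the maximum count observed).
    Classifies taxa as affiliated, candidate or unassigned from
    Greengenes-style lineage strings, and computes the coverage, overlap and
    sequencing-throughput statistics used to compare primer sets and their
    combination. Includes a degenerate-primer in-silico PCR engine for
    reference-database coverage evaluation, mock-community concordance
    checks, profile comparison by PCA and correlation-distance clustering,
    and a synthetic multi-primer data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
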