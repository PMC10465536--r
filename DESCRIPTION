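Package: rumenvirome
Title: Rumen Virome Analysis: vOTU Clustering, Host Linkage, Gene
    Curation and Virome Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rumen viral metagenomes downstream of raw
    viral detection. Clusters viral contigs into species-level viral
    operational taxonomic units (vOTUs) by average nucleotide identity and
    aligned fraction, assigns family-level taxonomy by a majority rule,
    links viruses to prokaryotic hosts through integrated-prophage
    alignments and exact CRISPR-spacer matches, curates auxiliary metabolic
    genes and antimicrobial resistance genes with genomic-context rules,
    and computes virome ecology summaries (trimmed-mean coverage,
    richness per Gbp, core-virome prevalence classes, shared-vOTU
    structure, study clustering). A seeded synthetic-community generator
    with planted ground truth makes every stage testable without external
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
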