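Package: piftools
Title: Analytics for PIF/Harbinger Transposon Insertion Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying the insertion
    landscape of PIF/Harbinger DNA transposons in plant genomes.
    Detects non-reference insertion loci from soft-clipped and
    discordant read evidence in transposon-display sequencing
    alignments, characterizes target-site duplication motifs and the
    chromatin context of insertion sites, annotates full-length and
    degenerate elements by terminal-inverted-repeat search combined
    with DAP-seq double-peak support, builds presence/absence
    neighbor-joining phylogenies across germplasm accessions, and maps
    causal loci in bulked segregants with the delta SNP-index. A
    seeded synthetic-data module generates every input the pipeline
    consumes together with truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
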