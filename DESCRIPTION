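Package: scafmate
Title: Semi-Automatic Genome Scaffolding from Mate-Pair Links
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Orders and orients pre-assembled contigs into scaffolds using
    mate-pair (long-insert paired read) link evidence. Before scaffolding,
    suspect chimeric contigs are flagged from their link neighbourhoods and
    contig copy numbers are estimated from coverage ratios; both verdict
    files are hand-editable and re-importable, supporting a semi-automatic
    workflow. A greedy iterative scaffold extender places big single-copy
    contigs, a small-contig inserter places the rest at link-congruent
    junctions, and gapped scaffold sequences are emitted with fixed 50-N
    gaps. Includes a read-consensus polymorphism corrector, a synthetic
    mate-pair dataset simulator for validation, and contiguity statistics
    (N50, LG50/LG75, genome coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
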