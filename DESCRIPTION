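Package: spacerscreen
Title: Informativeness Screening of Plastid and Nuclear Markers with
    Supermatrix Assembly and Distance Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate chloroplast intergenic spacers and introns for
    phylogenetic informativeness (indel events, transition and transversion
    substitutions, microsatellite loci, parsimony-informative sites, and sites
    diagnostic of a named clade split), extracts regions from annotated genome
    records, assembles selected loci into partitioned supermatrices, and
    verifies clade recovery with Kimura two-parameter distances,
    neighbor-joining and nonparametric bootstrap. Includes a sequence-evolution
    simulator with full ground-truth event logs for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
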