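Package: pubclassr
Title: Domain-Architecture Classification and Stress-Expression Profiling of
    Plant U-box E3 Ligases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing plant U-box (PUB) E3 ubiquitin ligase gene
    families. Classifies proteins into the ten PUB domain-architecture classes
    (with ARM-repeat II-a/II-b and kinase-domain IV subgroups) from InterProScan,
    hmmscan or simple tabular domain annotations; detects tandemly duplicated
    loci from a gene catalog; builds neighbor-joining trees with bootstrap
    support from amino-acid alignments; computes delta-delta-Ct relative
    expression with Student's t-tests and two-fold induction / three-fold
    suppression stress calls; and generates synthetic domain architectures,
    alignments evolved on known trees, and Cq tables with planted fold changes
    so every stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
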