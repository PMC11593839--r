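Package: dmdskip
Title: Reading-Frame Analysis of Exon-Skipping Strategies for Dystrophin Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Enumerates antisense-oligonucleotide exon-skipping strategies that
    restore the open reading frame of the dystrophin (DMD, Dp427m) transcript
    for large exon deletions, large duplications, and small intra-exonic or
    splice-site lesions. Implements the exon phase model of the 79-exon coding
    sequence, a minimal HGVS c.-notation parser for mutation intake, single-,
    double-, and multi-exon (cocktail) skip enumeration under the reading-frame
    rule, cohort-level applicability summaries by mutation class, and a seeded
    generator of synthetic mutation cohorts emulating the composition of
    locus-specific dystrophin mutation databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
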