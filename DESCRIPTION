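Package: crisprJunctions
Title: Prediction and Quantification of CRISPR/Cas9-Mediated Deletion and
    Inversion Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying chromosomal rearrangements engineered with
    paired CRISPR/Cas9 cuts. Locates sgRNA target sites under NGG/NAG PAM
    rules on both strands of linear or circular references, models blunt and
    staggered Cas9 cleavage (fixed cut 3 nt upstream of the PAM on the
    sgRNA-complementary strand, variable 3-8 nt on the protospacer strand),
    predicts deletion and inversion fusion-junction reference sequences,
    detects rearrangements by in-silico PCR, aligns amplicon reads to the
    predicted junctions, calls left-normalized indels around the fusion
    point, and explains observed indels mechanistically via overhang fill-in
    and resection of staggered breaks. Includes a synthetic-data module that
    emulates inverted-reporter plasmids, Lox-STOP-Lox cassettes, and two-cut
    genomic loci, and simulates error-bearing amplicon reads with truth
    labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
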