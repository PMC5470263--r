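Package: duphist
Title: Duplication-History Sites in Multigene Families under Concerted
    Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to separate alignment sites that trace the duplication
    history of a multigene family from sites homogenized by concerted
    evolution (intergenic gene conversion). Provides lineage-signature
    screening of gene family members against diagnostic-site tables,
    segmentation of alignment columns into local phylogenetic classes
    ("cacti") with a Viterbi assignment, a within-species
    maximum-distance statistic that discriminates duplication-history
    cacti from concerted-evolution cacti, uncorrected p-distances and
    neighbor-joining checks of lineage monophyly, and a forward
    simulator of two paralog lineages evolving along a species tree with
    tunable gene conversion. Includes an end-to-end recovery experiment
    quantifying how gene conversion erodes the footprints of
    duplication.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
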