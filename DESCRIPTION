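Package: karyotypeR
Title: Karyotype Characterization, Cytogenetic Marker Bookkeeping and ITS
    Phylogenetics for Plant Chromosome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for molecular-cytogenetic karyotype analysis from
    metaphase arm-length measurements: homolog-pair aggregation, relative
    lengths, arm ratios, centromeric indices, Levan centromere-position
    classification, karyotype formula strings, complement-level asymmetry
    statistics (Romero-Zarco A1/A2, As K%, Paszko AI) and Stebbins
    categories; bookkeeping for fluorochrome bands and 45S rDNA FISH sites
    including the di position statistic and Table-style marker codes;
    to-scale SVG idiogram rendering; ITS1-5.8S-ITS2 alignment statistics
    (GC content, variable and parsimony-informative sites, indel events,
    transition/transversion counts); and distance-based phylogenetics
    (p-distance, Kimura two-parameter, neighbour joining with nonparametric
    bootstrap, outgroup rooting, monophyly tests). A synthetic-data module
    generates measurement tables, marker sets and alignments with known
    ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
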