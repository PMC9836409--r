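Package: karyodelim
Title: Integrative Species Delimitation with Chromosome Fusion Models,
    COI Haplotype Networks and Wing-Colour Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative delimitation of cryptic butterfly taxa
    that differ by Robertsonian chromosome fusions and fissions. Implements
    a meiotic metaphase-I pairing model that predicts visible-element counts
    (bivalents and multivalents) for pure species, F1 hybrids and
    backcrosses from fusion-state karyotypes; DNA-barcode haplotype
    collapsing, minimum-spanning haplotype networks and haplogroup
    assignment; wing-colour morphometrics with non-metric multidimensional
    scaling and a permutation-based multivariate analysis of variance
    (PERMANOVA); a synthetic-study generator with planted truth; and an
    integrative per-specimen classifier combining mitochondrial haplogroup,
    karyotype and colour evidence to call species, F1 hybrids and
    backcrosses in a contact zone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    yaml,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
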