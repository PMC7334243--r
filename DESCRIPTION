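Package: karyostat
Title: Molecular Cytogenetic Karyotype Analysis and Idiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative karyotype analysis for plant molecular cytogenetics.
    Takes per-cell chromosome arm measurements and fluorochrome band / rDNA
    FISH site annotations and computes per-pair morphometrics (arm ratio,
    centromeric index, relative length), Levan morphology classes, karyotype
    formulae, the karyotype asymmetry suite (mean centromeric index, Romero
    Zarco A1 and A2, Arano AsK%, Paszko AI, Stebbins categories), marker
    position statistics (the di percent-distance statistic, CEN/PCEN/INT/TER
    classes, band amounts as percent of karyotype length, rDNA locus counts,
    colocalization), and relative-length-scaled idiograms rendered as SVG.
    Includes a synthetic-karyotype generator with built-in templates for five
    wild Vigna species (2n = 22) so the whole pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    optparse
Config/testthat/edition: 3
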