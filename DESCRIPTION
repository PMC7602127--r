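Package: chemocomp
Title: Comparative Untargeted LC-MS Metabolomics of Chemical Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A modular pipeline for objective comparison of chemical
    profiles from untargeted LC-MS and LC-MS/MS experiments. Detects and
    integrates MS1 chromatographic features from centroided mzXML/mzML
    runs, consolidates them across samples into a samples-by-features
    bucket table, relates samples by cosine-distance hierarchical
    clustering with cophenetic validation, ranks the features that drive
    group differences, and dereplicates features against a user-supplied
    reference compound table by exact adduct mass. An auxiliary MS2
    workflow bins fragmentation scans by precursor mass, filters for a
    diagnostic fragment ion, clusters scans by cosine distance and emits
    consensus spectra for annotating families of structural analogs. A
    synthetic LC-MS/MS data generator with full ground truth supports
    offline benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
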