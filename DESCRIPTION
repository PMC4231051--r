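Package: saltbridger
Title: Statistical Design of Thermostabilizing Salt Bridges on Protein Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surveys salt bridges across protein structures to build an
    empirical pairing-preference index, computes per-residue stability
    descriptors (relative solvent accessibility, weighted contact number,
    B-factor z-scores, conservation), and scores candidate charged
    substitutions with a weighted electrostatic attraction model to propose
    thermostabilizing mutations, including inter-subunit pairs on oligomers.
    Includes a synthetic-structure generator with fully known planted
    salt-bridge geometry for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
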