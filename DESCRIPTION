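Package: fgcorr
Title: Functional-Group Pairwise Corrections for Semiempirical Noncovalent Interaction Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying functional-group corrections (FGC) to
    semiempirical quantum mechanical (SQM) interaction energies such as PM6. The
    correction is a pairwise Buckingham-type potential, A*exp(-B*r) + C/r^n, damped at
    short range by a sigmoid cutoff, summed over intermolecular atom pairs classified by
    force-field-style atom types. The package reads XYZ geometries, assigns atom types by
    rule, generates rigid-body intermolecular potential energy curve (IPEC) scans,
    evaluates correction energies and analytic gradients, fits correction parameters to
    reference-minus-SQM energy differences by a genetic-algorithm least-squares procedure
    with local polishing, and reports validation statistics (MAE, MBE, linear
    correlation). A synthetic-data generator with known ground truth supports end-to-end
    testing without any electronic-structure computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
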