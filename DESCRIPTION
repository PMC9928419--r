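Package: rpitriage
Title: Triage of Small-Molecule Inhibitors of RNA-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for triaging small-molecule inhibitors of
    RNA:protein interactions. Implements a molecular-dynamics-derived filter
    score combining ligand-protein versus ligand-water interaction enthalpies
    with an interatomic contact ratio; absolute binding free energy bookkeeping
    (Bennett acceptance ratio estimation over lambda windows, the analytical
    orientational-restraint correction, thermodynamic-cycle assembly and
    free-energy to dissociation-constant conversion); isothermal titration
    calorimetry one-site isotherm fitting; NMR chemical shift perturbation
    analytics (weighted-average CSPs, pocket averages, PCA mining with
    SPE/Hotelling T2 outlier tests and clustering, scalar-product competition
    analysis, saturation transfer difference quantities, titration linearity);
    and high-content-screening plate scoring for microtubule-bench assays
    (spot detection and shape filtering, per-well enrichment-slope regression,
    plate normalization, strictly standardized mean difference, hit calling,
    and four-parameter-logistic dose-response fitting). Seeded synthetic-data
    generators emulate the statistical structure of every input so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
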