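Package: fibrilmech
Title: Mechanosensitive Calcium Binding Analysis for Fibrillin-1 cbEGF Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for constant-velocity pulling simulations of
    fibrillin-1 calcium-binding EGF-like (cbEGF) domain pairs. Reconstructs
    equilibrium potential-of-mean-force profiles from nonequilibrium work
    ensembles via the Jarzynski equality, derives smoothed force profiles and
    scalar summaries (free-energy change over a strain interval, peak and
    windowed mean forces, percent changes), computes equilibrium conformational
    metrics (two-domain length, straightness, apparent stiffness modulus),
    quantifies mechanosensitive calcium binding through contact counts and
    Shrake-Rupley solvent-accessible surface area with work-weighted ensemble
    averaging, and reproduces a Marfan-syndrome mutation-cohort classification
    analysis (disease-keyword filtering, domain assignment, residue-class and
    disulfide-bond classification, chi-squared cohort comparison). A synthetic
    steered-Langevin generator with analytically known free-energy profiles
    supplies every input the pipeline needs, so the full analysis is testable
    without molecular dynamics output or database access.
License: MIT + file LICENSE
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
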