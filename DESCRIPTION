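Package: catchbond
Title: Structure-Based Catch-Slip Bond Models for TCR-pMHC Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kramers-theory models of force-dependent receptor-ligand
    dissociation in which the energy landscape is deformed by a
    polymer-mechanics extension functional, specialised to T-cell receptor
    bonds with class I and class II peptide-MHC complexes. Provides
    freely-jointed-chain and extensible worm-like-chain force-extension laws,
    the linear-cubic landscape and its force-dependent off-rate, catch-slip
    existence analysis and phase diagrams, Levenberg-Marquardt fitting of
    bond-lifetime-versus-force data with mean +/- SEM refit uncertainties,
    bond-profile metrics including the catch-bond intensity, cohort analyses
    (Lloyd's k-means clustering, PCA with Mahalanobis distances, potency
    correlations, cross-class model examination), and a seeded simulator of
    biomembrane-force-probe style lifetime datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
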