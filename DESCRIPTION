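Package: octavd
Title: Parafoveal Vessel Density from OCT Angiography with Local and
    Global Binarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies parafoveal vessel density in en face optical
    coherence tomography angiography (OCTA) images of the superficial
    capillary plexus. Implements multiscale Frangi vesselness
    enhancement, five binarization strategies (Phansalkar, sliding-window
    Otsu, adaptive mean, global mean, global Otsu), laterality-aware
    ETDRS inner-grid quadrant geometry anchored on the foveal avascular
    zone, and mixed-design repeated-measures ANOVA with
    Greenhouse-Geisser correction and Tukey post hoc comparisons. A
    synthetic angiogram generator produces phantom cohorts with
    group-wise capillary dropout so the local-versus-global
    discrimination experiment can be reproduced without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
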