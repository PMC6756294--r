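Package: dsegr
Title: Diffusion Tensor Segmentation Spectra and the DSEG-theta Biomarker
Version: 0.1.0
Authors@R: person("SCANS", "Reimplementation", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments the two-dimensional isotropic/anisotropic (p,q)
    diffusion plane of the cerebrum into sixteen microstructural segments by
    k-medians clustering of the pooled (p,q) histogram, summarises each scan
    as a sixteen-component volume-percentage spectrum, and scores scans with
    the spectral angle (DSEG-theta) against an iteratively selected healthy
    reference spectrum. Downstream stages model longitudinal change in theta
    and cognitive composites with linear mixed-effects models, regress
    per-subject cognitive slopes on baseline theta and theta change, estimate
    dementia-conversion risk with Cox proportional hazards, and classify
    converters with leave-one-out cross-validated linear discriminant
    analysis. A synthetic-cohort generator produces longitudinal phantom
    imaging, cognition, and conversion data with known ground truth so every
    stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
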