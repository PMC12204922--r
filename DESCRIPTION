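Package: mvwss
Title: Multi-View Deep-Learning Surrogate for Wall Shear Stress on Aortic Aneurysm Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid surrogate prediction of time-averaged wall shear stress
    (TAWSS) maps on abdominal-aortic-aneurysm surface geometries. Provides a
    domain transformation that renders triangulated vessel surfaces into rings
    of fixed-size snapshot images through an invertible colormap codec, a
    nested-skip-connection encoder-decoder network (MultiViewUNet) trained with
    a background-masked mean-squared-error loss, masked image-quality metrics
    on the stress scale, a procedural generator of aneurysm-like geometries
    with an analytic pseudo-CFD wall-shear-stress oracle, and an end-to-end
    reproducible pipeline (generate, render, split, train, evaluate).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
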