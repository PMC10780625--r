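Package: dendrostand
Title: Spatial Patterns, Tree-Ring Chronologies and Climate Response in
    Multi-Aged Forest Stands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dendroecological analysis of multi-aged, mapped
    forest stands. Implements univariate and bivariate Ripley's K / Besag's
    L point-pattern statistics with Monte Carlo confidence envelopes on
    circular plots, tree-ring series management (cross-dating screening,
    pith-offset estimation, coring-height age correction, biometric
    screening), chronology construction with spline, negative-exponential
    and regional-curve standardization, and bootstrap orthogonalized
    response functions of ring-width indices on monthly climate regressors
    over the biological year. Includes simulators for stem maps, ring-width
    series and Mediterranean monthly climate so that every stage of the
    pipeline can be exercised and validated on synthetic data, plus
    readers and writers for stem-map CSV, Tucson RWL and monthly climate
    CSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
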