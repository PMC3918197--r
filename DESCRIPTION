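Package: pelletdose
Title: TG-43U1 Dose Engine for Cs-137 Selectron Pellet-Train Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treatment-planning dose engine for low-dose-rate Cs-137
    Selectron-style pellet-train brachytherapy based on the AAPM TG-43U1
    formalism. Provides tabulated radial dose function and 2D anisotropy
    function containers with interpolation and file I/O, single-source
    dose-rate evaluation with the point-source geometry function,
    superposition of per-pellet doses over arbitrary active/inactive pellet
    configurations, a legacy exposure-rate-constant comparator engine
    (inverse square law with Meisberger tissue attenuation), dose grids,
    isodose contour extraction and engine-vs-engine percent-difference maps,
    and extraction of TG-43U1 parameters (dose-rate constant, g(r), F(r,theta),
    air-kerma strength) from sampled single-source dose distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
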