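Package: bluederm
Title: Blue-Light Phototherapy Dynamics of Psoriatic Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic compartment model of healthy and diseased
    keratinocyte population dynamics in psoriatic epidermis under blue-light
    phototherapy. Twelve ordinary differential equations track six
    differentiation stages (stem, transit amplifying, growth arrested,
    spinous, granular, corneocyte) for a healthy and a diseased lineage
    sharing a stem-cell niche, with fluence-dependent blue-light factors
    acting on proliferation, division/differentiation and apoptosis rates.
    Includes treatment-protocol calendars (continuous and pulsed
    irradiation), a local psoriasis severity index derived from total cell
    density, a thirteen-case mechanism-hypothesis screen, fluence and
    treatment-length scans with bistability phase diagrams, multi-parametric
    (Latin hypercube + Kolmogorov-Smirnov) and local sensitivity analyses,
    dose-response coefficient calibration with a synthetic in-vitro data
    generator, configuration files, run manifests, SBML-style model
    exchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
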