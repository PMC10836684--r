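Package: mapdh
Title: Multi-Domain Automated Photopatterning of DNA-Functionalized
    Hydrogels, Simulated End-to-End
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design, virtually execute, and quantify multi-domain
    DNA-functionalized hydrogel photopatterning experiments without
    hardware. Compiles raster images into per-domain binary location maps
    (binning plus k-means color clustering), schedules validated
    flow/pattern/wash command streams for a digital-micromirror
    photopatterning instrument, executes protocols against a simulated
    microfluidic chamber (photopolymerization, sacrificial-layer lift-off
    and collection, addressable quenching by DNA hybridization, and
    hybridization-chain-reaction driven swelling), renders synthetic
    multi-channel fluorescence micrographs, and measures hydrogel geometry
    and fluorescence via Otsu binarization and connected-component sizing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
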