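Package: printfid
Title: Layer-Wise Printing Accuracy Assessment for Extrusion 3D Food Printing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of layer-wise printing fidelity for
    extrusion-based 3D food printing. Parses RepRap-flavour G-code into metric
    toolpaths, rasterizes digital layer images with a flattened-filament width
    model, rectifies top-view photographs onto a metric reference frame using
    green fiducial markers, segments the printed object, and quantifies
    over- and under-extrusion by set logic against the digital design. Defects
    are localized as percentile-normalized grid index heatmaps, and image-click
    survey responses are aggregated into click-frequency heatmaps with a
    rating-versus-marks association. A synthetic fixture generator produces
    design toolpaths, simulated prints with parameterized defects and exact
    ground-truth ledgers, photographed scenes, and survey tables, so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
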