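Package: saxsbeam
Title: Beam Orientation Optimization for Small-Angle X-Ray Scattering from Deep Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward model of small-angle X-ray scattering (SAXS) profiles from
    deep targets embedded in large attenuating objects, such as amyloid-rich
    brain regions interrogated through the human head with an X-ray pencil
    beam. Computes scattering-vector smearing from target-to-detector distance
    uncertainty, Beer-Lambert attenuation along chord paths, and triangular
    detector-blur convolution; scores candidate beam paths through analytic
    phantoms or segmented 2D raster masks with a conspicuity-per-dose figure
    of merit and ranks them for acquisition planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    pracma,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
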