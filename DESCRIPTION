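Package: magsense
Title: Tissue Property Sensing with Magnetoelastic Soft Robots
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling for wireless magnetoelastic
    soft-robot tissue sensing. Implements a quasi-static elastica model of a
    magnetized beam-like robot under uniform magnetic fields, inverse
    estimators that recover tissue adhesion (and pH via calibrated adhesive
    patches) from buckled robot shapes at the detachment threshold, and
    frequency-sweep estimators of tissue storage and loss moduli from the
    dynamic interface strain response. Includes the supporting imaging
    pipeline (robot centerline tracking, digital image correlation of
    tracer-particle images, misalignment correction, wavelet-based stiffness
    inclusion localization), a synthetic-data generator that emulates
    detachment and undulation experiments, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
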