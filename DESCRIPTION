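Package: octstiff
Title: Non-Contact Skin Stiffness from Air-Jet Indentation OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies skin stiffness from optical coherence tomography
    (OCT) B-scan time series acquired under non-contact air-jet
    indentation. Provides a speckle phantom simulator with known layer
    geometry and ground-truth stiffness, the grayscale/crop/Gaussian
    image-conditioning chain, a U-Net encoder-decoder for stratum-corneum
    segmentation trained and evaluated on CPU, displacement tracking of
    the segmented layer over a baseline/pressure/recovery protocol, the
    structural stiffness coefficient K = F / delta-d, and the reliability
    and comparison statistics used in air-jet elastography studies
    (one-way ANOVA with LSD post hoc, Student's t, two-way mixed ICC with
    confidence intervals, Cohen's d, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
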