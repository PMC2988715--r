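Package: pentachroma
Title: Spectral Sensitivity, Cone Mechanisms and Opsin Expression in Cichlid
    Color Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrophysiological studies of fish color
    vision. Fits Naka-Rushton response-intensity functions to electroretinogram
    data and builds relative spectral-sensitivity curves; constructs A1/A2
    visual-pigment absorbance templates with chromophore-mixture lambda-max
    shifts and lens-transmission correction; identifies functional cone
    mechanisms across chromatic-adaptation backgrounds and estimates retinal
    A2 proportion from the long-wavelength limb; reconstructs sensitivity with
    a multiple-cone mechanism (opponency) model; computes photoreceptor quantum
    catches; derives relative cone-opsin expression from qPCR quantification
    cycles; and provides cohort-level frequency statistics including an exact
    Fisher test by complete enumeration. A synthetic-cohort generator with
    known ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
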