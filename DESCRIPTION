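Package: canalvol
Title: Volumetric Quantification of Superior Semicircular Canal Plugging from T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to visualize and quantify the plugging status of a superior
    semicircular canal from pre- and post-operative heavily T2-weighted MRI
    volumes. Implements region-restricted Otsu thresholding of the labyrinth
    fluid signal, rigid alignment of scan pairs (including a contralateral
    mirror-flip mode for patients without a preoperative scan), extraction of
    the filling defect as the overlap difference of the segmented labyrinths,
    relative-volume quantification of the defect, mask-restricted direct
    volume rendering of the result, and intraclass correlation statistics for
    inter-rater agreement. A parametric synthetic labyrinth phantom generator
    with exact ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
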