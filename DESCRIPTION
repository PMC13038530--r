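Package: pibsim
Title: Prior Information-Based Subtraction Radiography Simulation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a digital thorax study (planning CT plus rigidly shifted
    treatment-day CTs of an anthropomorphic phantom with a mobile lung tumor),
    removes non-essential tissue signal from treatment-day radiographs by
    subtracting digitally reconstructed radiographs of the tissues outside the
    thoracic cavity, and quantifies the resulting gain in lung-tumor visibility
    and markerless trackability. Includes an exact-path cone-beam projector,
    rigid 3D/3D and orthogonal-pair 2D/2D bone-driven registration, HU-domain
    volume operations, contrast-to-noise and motion-trace evaluation, and
    readers/writers for MetaImage, NRRD and NIfTI volumes and 16-bit radiographs
    with JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    RNifti,
    tiff,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    ggplot2,
    withr
Config/testthat/edition: 3
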