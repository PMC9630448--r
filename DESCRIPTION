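Package: pbiphase
Title: Discrete Phase Retrieval for Propagation-Based X-Ray Phase-Contrast
    Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-distance transport-of-intensity phase retrieval for
    propagation-based X-ray phase-contrast imaging, implementing both the
    classical Lorentzian Fourier filter built on the continuous Fourier
    derivative theorem and its discrete-mathematics rederivation that uses
    the cosine (five-point Laplacian) frequency kernel. Includes
    transfer-function and detector point-spread-function analysis, a
    linearised transport-of-intensity forward simulator with end-on
    cylinder phantoms, azimuthal line-spread-function metrology with
    Pearson VII fitting, parallel-beam filtered back projection, the
    two-material retrieval filter, and dual-energy photoelectric and
    electron-density decomposition with either frequency kernel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
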