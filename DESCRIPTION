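Package: parosc
Title: Cell-Cycle-Entrained PAR Polarity Models and Cortical Image Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantification tools for PAR polarity networks whose
    mutual-antagonism feedback oscillates with the cell cycle. Implements a
    two-compartment four-ODE PAR model with time-varying P-to-A feedback and
    orientation cues, stochastic (Euler-Maruyama) polarity landscapes with
    occupancy-based quasipotentials, a one-species wave-pinning model with a
    stationary Fokker-Planck solver, a full 1D reaction-diffusion PAR model
    with P1/P2 polarization scenarios, and an image-quantification pipeline
    (membrane straightening, Gaussian/erf cross-profile fits, asymmetry index,
    profile alignment, difference-of-Gaussians background subtraction and
    Laplacian-of-Gaussian cluster detection) exercised on synthetic embryo
    images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    jsonlite
Config/testthat/edition: 3
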