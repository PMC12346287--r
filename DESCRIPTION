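Package: holotomo
Title: Multiplexed Optical Diffraction Tomography with Fourier-Plane Pattern Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for high-speed optical diffraction tomography with
    multiplexed plane-wave illumination. Designs binary spot patterns for a
    digital micromirror device (DMD) conjugate to the objective back focal
    plane, including angle and position multiplexing and an iterative
    partition optimizer; simulates holograms with a scalar Mie partial-wave
    oracle and multislice forward models (beam propagation and split-step
    non-paraxial); recovers complex fields from off-axis holograms with
    weighted least-squares phase unwrapping; initializes the refractive
    index by low-resolution Rytov demultiplexing on the Ewald sphere; and
    reconstructs 3D refractive index by FISTA proximal-gradient descent
    with total-variation and l1 regularization. Includes synthetic scene
    generators (Brownian colloids with hindered diffusion near a wall,
    wobbling microswimmers) and 3D particle localization, linking, and
    diffusion/wobble statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
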