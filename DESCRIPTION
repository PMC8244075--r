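Package: pamrs
Title: Powder-Averaged Analysis of Diffusion-Weighted MR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models and estimation tools for powder-averaged (spherically
    averaged) diffusion-weighted MR spectroscopy of brain metabolites.
    Implements the orientation-averaged axisymmetric-tensor and "stick"
    compartment signal models with constrained nonlinear least-squares
    fitting, microscopic fractional anisotropy and compartment mean
    diffusivity, macroscopic (voxel-averaged) diffusion-tensor estimation
    with a dispersed-stick angular-spread summary, electrostatic
    gradient-direction scheme design, bipolar diffusion-encoding waveform
    synthesis with full b-matrix computation, noise-propagation and
    rotational-variance simulation studies, and Monte Carlo random-walk
    simulation of restricted diffusion in impermeable cylinders. A
    synthetic-data generator emulates directional metabolite acquisitions
    from dispersed-fiber substrates for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
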