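Package: nanocagebench
Title: Fluorescent-Protein Benchmarking with Self-Assembling Nanocages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative comparison of fluorescent proteins (FPs) imaged as
    FP-tagged 60-subunit protein nanocages in live cells. Provides a synthetic
    fluorescence-microscopy generator (diffusing sub-diffraction particles,
    exposure-integrated motion blur, exponential photobleaching, Poisson shot
    noise and camera read noise), sub-pixel 2D Gaussian spot fitting with
    background-corrected two-standard-deviation disc integration, whole-cell
    photobleaching half-life estimation by exponential decay fitting,
    single-particle tracking with optimal frame-to-frame assignment and
    diffusion-coefficient estimation from averaged mean-square-displacement
    curves, and FP comparison statistics (relative brightness, emission yield,
    one-way ANOVA with Tukey-Kramer HSD and compact letter displays), plus
    Fibonacci-lattice fluorophore spacing and spectral throughput utilities.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
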