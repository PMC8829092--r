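Package: spt2d
Title: Single-Particle Tracking, Simulation and Diffusion-Model Analysis in 2D
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolchain for two-dimensional single-particle tracking (SPT)
    experiments. Detects and links particles in time-lapse TIFF stacks
    (spot-enhancing Laplacian-of-Gaussian filter, radial-symmetry sub-pixel
    localisation, Hungarian frame-to-frame linking with gap filling),
    analyses trajectories with localisation-error- and motion-blur-aware
    mean-squared-displacement (MSD) and apparent-diffusion-coefficient (ADC)
    pipelines with BIC-based diffusion-model selection, and simulates
    ground-truth Brownian and hop-diffusion trajectories plus synthetic
    noise-corrupted movies to validate every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    tiff,
    EBImage,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    clue
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'trackio.R'
    'msd.R'
    'models.R'
    'adc.R'
    'simulate.R'
    'movie.R'
    'hungarian.R'
    'tracker.R'
    'cli.R'
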