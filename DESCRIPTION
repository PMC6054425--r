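Package: plumeMI
Title: Information-Theoretic Analysis of Odor-Plume Sampling Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how many bits of information about sampling location
    are conveyed by discretized odor-concentration samples drawn from a
    turbulent plume, under different allocations of coding resources
    (concentration resolution, number of spatial sensors, number of temporal
    samples). Provides seedable synthetic plume generators (a Gaussian-puff
    advection model and an analytically tractable on/off whiff surrogate),
    quantizer design by histogram equalization and by greedy mutual-information
    maximization, plug-in entropy and mutual-information estimators with
    finite-sample bias correction by 1/N extrapolation, and pipeline
    orchestration over sampling grids with rigid jitter envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'plume-io.R'
    'synthetic-plume.R'
    'encoding.R'
    'infotheory.R'
    'pipeline.R'
    'plumeMI-package.R'
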