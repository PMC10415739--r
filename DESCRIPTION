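Package: dropletTMSD
Title: Compartmentalized Toehold-Mediated Strand Displacement Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of toehold-mediated DNA strand
    displacement (TMSD) reactions compartmentalized in water-in-oil
    emulsion droplets, with or without a random-sequence oligonucleotide
    background. Provides a nearest-neighbor thermodynamic model of
    invader sequestration by a random pool (Boltzmann binding
    probabilities, two-state bound fractions, and the top-decile
    sequestration statistic), a droplet encapsulation model (sizes,
    mixing ratios from sinusoidal pressure programs, Poisson
    partitioning of pool molecules), a deterministic second-order
    kinetics engine with a closed-form oracle, a two-channel synthetic
    fluorescence trace generator with configurable noise and quality
    control artifacts, and the downstream analysis pipeline: trace
    filtering, reference-dye normalization, initial-slope estimation,
    droplet-to-droplet variability statistics, rate-constant fitting,
    and stoichiometry mapping against the mixing-ratio parabola.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
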