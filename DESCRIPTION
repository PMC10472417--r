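Package: hdesi
Title: High-Density EEG Electric Source Imaging of Interictal Spikes
Version: 0.1.0
Authors@R: person("hdesi", "maintainers", email = "maintainers@hdesi.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for interictal electric source
    imaging on high-density scalp EEG. Provides an analytic three-shell
    spherical forward model with quasi-uniform electrode montages, a
    ground-truthed synthetic recording generator with embedded spike-wave
    events and 1/f background, a matched-filter spike detector with
    probability thresholding and peak-electrode clustering, epoch extraction
    and averaging with half-rise timing, a depth-weighted minimum-norm
    (wMNE) inverse operator, distance-to-resection and sublobar concordance
    scoring, and a spike-count subsampling experiment quantifying how the
    number of averaged spikes affects source-maximum localization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
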