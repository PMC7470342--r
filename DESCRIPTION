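Package: estuarysound
Title: Estuarine Soundscape Phenology from Duty-Cycled Hydrophone Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive-acoustic-monitoring analysis of estuarine
    soundscapes: calibrated band-limited rms sound pressure levels (SPL, dB
    re 1 uPa) from duty-cycled recordings via Welch spectral estimation,
    on-the-hour subsampling and flag-based exclusion of physical and
    anthropogenic sound, lunar/tidal/diel covariate annotation, Bayesian
    change-point detection of the spring onset of snapping-shrimp and fish
    acoustic activity (Barry-Hartigan product partition model with a Gibbs
    sampler), shadow-feature random-forest variable importance for SPL
    drivers, Dunnett-Tukey-Kramer pairwise comparisons, seine-survey
    diversity metrics, and soundscape-biodiversity correlation. Includes a
    synthetic soundscape generator (environmental series, SPL tables, raw
    audio clips, seine catches) so the full pipeline is testable without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
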