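Package: eegstress
Title: Emotional Stress Detection from EEG with Genetic-Algorithm Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for binary emotional-stress detection from multichannel
    EEG recordings rated on arousal/valence scales. Annotates trials as calm or
    stress from self-assessment ratings, segments trials into short windows,
    extracts a named feature bank (time-domain statistics, Welch band power,
    higher-order crossings, Hjorth parameters, frontal alpha asymmetry),
    reduces the feature space either by a genetic algorithm driven by a
    class-separability fitness or by a PCA baseline, and classifies segments
    with k-nearest neighbours under stratified k-fold validation. Includes a
    seeded synthetic cohort generator with planted band-power and asymmetry
    effects so the full pipeline is testable without access-restricted EEG
    datasets, plus a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    class,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
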