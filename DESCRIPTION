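Package: lickspt
Title: Lick Microstructure and Sucrose Preference Analysis for Home-Cage Lickometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-bottle sucrose preference tests (SPT)
    recorded with contact lickometers. Detects individual licks in voltage
    traces (peak prominence and width criteria, double-peak exclusion),
    computes lick microstructure (interlick-interval classification into
    bursts, clusters and pauses; bout segmentation; temporal binning),
    derives session-level preference and memory metrics (quick switches
    between bottles, returns to a bottle after long pauses), performs
    volume-versus-lick quality control, averages test nights with
    side-switch bookkeeping, and classifies stress phenotypes by a
    preference cutoff. Includes a generative simulator of overnight
    mouse drinking sessions (circadian bout-initiation process, ILI
    mixture, location memory, recording artifacts) so the whole pipeline
    can be exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
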