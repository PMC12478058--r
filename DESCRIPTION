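Package: optopattern
Title: Biomimetic Optogenetic Stimulation Patterns from Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating biomimetic optogenetic
    stimulation. Classifies putative GABAergic midbrain units from sorted
    extracellular spike trains using peak-to-trough time and baseline firing
    rate, detects bursts with a four-parameter interval algorithm, converts
    spike trains into laser pulse schedules (biomimetic playback, ISI-shuffled
    surrogates, frequency-matched tonic trains, and continuous duty cycles),
    renders schedules to normalized square-wave and TTL event formats, and
    simulates gated pattern delivery in real-time place-preference sessions
    with preference scoring. Includes seeded generators for irregular
    (gamma-renewal) spike trains, biphasic unit waveforms, and compartment
    occupancy traces so every stage is testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
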