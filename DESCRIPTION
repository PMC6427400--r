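Package: wingbeatr
Title: Detection and Classification of Fruit-Fly Wing-Beat Signals from
    Optoelectronic Sensor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wing-beat signals of fruit flies (Diptera:
    Tephritidae) recorded with an infrared optoelectronic sensor. Implements
    sliding-window RMS passage-event detection, automatic feature extraction
    by autocorrelation and zero-padded FFT (fundamental frequency and
    harmonic components), statistical species characterization with outlier
    and octave-error handling, and two-species discrimination of Anastrepha
    fraterculus and Ceratitis capitata from the overlap of per-feature
    normal models. Includes a synthetic signal simulator that emulates
    passage events, background noise, mains hum, luminosity drift and the
    analog sensor chain, so the full pipeline can be exercised and validated
    without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
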