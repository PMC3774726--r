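Package: terma
Title: Knowledge-Based QRS Detection with Two Event-Related Moving Averages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects QRS complexes (heartbeats) in single-lead ECG signals
    using two event-related moving averages of the band-pass filtered and
    squared signal, with a dynamic threshold derived from the signal mean.
    Includes a brute-force grid optimizer for the detector's five
    parameters, beat-matching evaluation (sensitivity and positive
    predictivity), a Pan-Tompkins comparator detector, a seeded synthetic
    ECG generator with ground-truth R peaks and configurable noise, readers
    and writers for plain-text and WFDB signal/annotation files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
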