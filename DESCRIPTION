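Package: ecgait
Title: Mouse ECG Rhythm and Open-Field Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-lead mouse electrocardiograms and
    open-field gait trajectories. Detects R peaks (negative-deflection lead
    convention), derives cycle periods, and computes per-recording heart rate,
    its standard deviation, and a per-cycle rhythm irregularity score
    (100*|Pn - Pn-1|/Pn-1 over 50-cycle windows). Computes gait distance,
    maximum and average speed from tracked centroid trajectories. Provides
    paired (Wilcoxon signed-rank) and unpaired (Mann-Whitney U) nonparametric
    group comparisons with exact small-sample enumeration, and a synthetic-data
    generator that emulates mouse ECG (600-750 beats/min, configurable jitter
    and arrhythmic events) and wild-type versus hypoactive gait profiles so the
    full pipeline is testable without animal recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
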