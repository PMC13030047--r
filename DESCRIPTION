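Package: lmdstress
Title: Environment-Based Stress Location Mapping for Low-Speed Mobility Travel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies likely stress locations along low-speed mobility device
    (e.g., powered wheelchair) routes from environmental sensor streams. Divides
    a route into fixed-length segments by geodesic chainage, matches segment
    boundaries to a 1 Hz GPS trajectory, quantifies per-segment stress factors
    (vertical-vibration RMS, unique-person encounters, sidewalk width),
    classifies each factor into three intensity levels, and combines them into
    a Composite Stress Score with Low/Moderate/High labels. Companion
    heart-rate-variability tooling cleans RR-interval series (ectopic bounds,
    Hampel and quotient filters, cubic-spline interpolation) and computes
    per-segment SDNN, RMSSD and pNN50 with per-participant z-scoring.
    Validation utilities provide bootstrap Spearman correlations between the
    composite score and HRV, Fisher-z power calculations, and within-subject
    segment comparisons. A seeded synthetic-ride generator with ground-truth
    stress structure makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
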