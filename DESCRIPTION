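Package: divekit
Title: Dive Abstraction, Drift-Rate Body-Condition and Aerobic-Limit
    Analysis for Juvenile Elephant Seal Biologging Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing satellite-relayed dive records from
    southern elephant seals during their first year at sea. Reduces 1-Hz
    depth profiles to broken-stick segment summaries (descent, bottom,
    ascent), detects passive drift segments with a five-step filter and
    estimates per-dive drift rates as a proxy for body condition,
    delineates foraging-trip phases (departure, central, return) from the
    smoothed drift-rate trajectory including the switch to positive
    buoyancy, and performs aerobic-dive-limit analyses (phase-wise
    theoretical-ADL exceedance, behavioural-ADL breakpoint detection on
    the surface-versus-dive-duration relation, post-dive surface-duration
    relations to swimming effort and prey-catch-attempt rate). Includes a
    calibrated synthetic trip generator with known ground truth for
    recovery testing of the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
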