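Package: acidbase
Title: Dual-Model Acid-Base Analysis (Boston and Stewart) for Clinical Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interprets arterial blood gas and serum chemistry panels with
    the traditional CO2/HCO3 (Boston) workflow and the physicochemical
    (Stewart) workflow. Computes anion gap and albumin-corrected anion gap,
    expected bicarbonate under respiratory-alkalosis compensation, the total
    non-volatile weak acid concentration (A_TOT), apparent and effective
    strong ion differences (SIDa, SIDe), the strong ion gap (SIG), and
    delta-based classification of normal- and increased-anion-gap metabolic
    disturbance. Ships a transcribed 29-patient nephrotic-syndrome reference
    cohort with its published per-patient and summary values, a reproduction
    report that recomputes them, cohort summaries (nearest-rank quantiles,
    threshold counts, OLS and polynomial fits), a urinary anion gap and
    renin/aldosterone categorizer, and a seeded synthetic-cohort generator
    for pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
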