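Package: lymphpk
Title: Lymphatic Transport Pharmacokinetics for Lymph-Duct-Cannulated Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental pharmacokinetic analysis and lymphatic
    bioavailability partitioning for lymph-duct-cannulated animal studies.
    Computes cumulative lymphatic transport from interval lymph collections,
    absolute bioavailability via lymph (F_AL) by direct mass balance,
    absolute bioavailability via the portal vein (F_AP) from dose-normalized
    oral/intravenous AUC ratios, and the total and relative lymphatic
    bioavailability (F, F_RL). Includes a mechanistic linear-compartment
    simulator of a cannulated-animal cross-over study with an external lymph
    sink, so that every estimation stage can be validated by parameter
    recovery, plus paired/unpaired comparison statistics and
    publication-style summary tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
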