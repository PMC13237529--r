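Package: oncotriage
Title: Rule-Based Digital Symptom Triage and Episode Analytics for
    Systemic Anticancer Therapy Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for operating and evaluating a red/amber/green digital
    symptom-triage service for patients on systemic anticancer therapy.
    Daily ordinal symptom check-ins (11 symptoms, 0-3 severity) are mapped
    to acuity tiers under a configurable triage policy; amber and red
    alerts are consolidated into episode-level review events by a rolling
    48-hour window with symptom-domain continuity; service analytics cover
    engagement, alert distribution, per-patient red-alert burden,
    response timeliness and escalation pathways; structured safety
    case-finding cross-references acute-care encounters against a 48-hour
    lookback of check-ins and alerts. A seeded synthetic cohort generator
    reproduces the statistical structure of a monitored outpatient cohort
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
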