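Package: fullcycle
Title: Full Annual Cycle Energetics and Time Budgets from GPS and
    Accelerometer Biologging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs daily energy expenditure and time-activity budgets of
    migratory birds across the full annual cycle from GPS and tri-axial
    acceleration biologging records. Converts 1-s acceleration bursts to dynamic
    body acceleration (VeDBA), estimates per-fix metabolic rates from activity
    and from a heat-exchange thermoregulation model, segments bird-years into
    breeding, migration and wintering stages using net-displacement rules and
    kernel density estimates of wintering areas, fills winter data gaps by
    resampling within stationary periods, and computes annual summaries such as
    annual energy expenditure, sum of deviance, extreme weeks and migration-day
    tables. Includes a synthetic track generator emulating four migration
    strategies of lesser black-backed gulls for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
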