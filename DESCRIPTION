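Package: pape
Title: Personal Air Pollution Exposure Estimation from Fixed-Site Monitors,
    Indoor Sensors and Activity Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the personal air pollution exposure (PAPE, in
    micrograms inhaled) of an individual by combining hourly fixed-site
    outdoor monitoring data, an indoor air-quality monitor stream, a
    Bluetooth e-beacon presence log and a time-activity trace.  Outdoor
    concentration surfaces are interpolated per hour by inverse-distance
    weighting, simple/ordinary kriging or collocated co-kriging, with the
    technique and its variogram parameters chosen by grid search under
    k-fold cross-validation on the root-mean-squared error.  Indoor
    presence is segmented from beacon pings by a maximum-gap rule, the
    matched monitor readings are time-integrated by the trapezoidal rule,
    and indoor and outdoor doses are merged along the activity timeline
    with activity-specific minute-ventilation weights.  Candidate travel
    routes can be ranked by their predicted exposure.  A synthetic-data
    generator emulates all five input streams with controlled ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
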