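Package: rtflowsim
Title: Discrete-Event Simulation of Radiotherapy Pre-Treatment Patient Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-event simulation of the pre-treatment workflow of a
    radiotherapy department, from consultation through imaging, image
    post-processing, contouring and treatment planning to the first
    irradiation session. Patients arrive according to weekday-dependent
    Poisson processes and are assigned a care plan, urgency level and
    imaging/planning steps from a configurable catalogue. First-fraction
    dates are set either at consultation (pull strategy) or at the start of
    treatment planning (push strategy); machines are booked into labeled
    slot calendars and contouring/planning tasks are dispatched to staff on
    an earliest-due-date basis. The package computes waiting times, target
    breaches and rebook counts with warm-up and replication analysis, and
    drives workflow-control sweeps and capacity/scheduling scenario
    experiments under common random numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
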