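Package: csftwin
Title: Lumped-Parameter Digital Twin of Craniospinal CSF Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile cerebrospinal fluid (CSF) flow and pressure in a
    lumped-parameter hydraulic replica of the craniospinal system: an
    arteriovenous (AV) driving waveform, two nonlinear air-chamber compliance
    units obeying the isentropic gas law, adjustable valve resistances, and a
    segmented spinal canal with Hagen-Poiseuille resistance. Provides waveform
    synthesis for cardiac-gated cervical CSF flow cohorts, valve-resistance
    calibration against measured bidirectional flow extrema, cam-disc profile
    generation for a piston pump from a target flow waveform, and intracranial
    pressure (ICP) pulse analysis (mean wave amplitude, P2:P1 ratio) together
    with stroke-volume and flow-timing metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
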