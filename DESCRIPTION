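Package: retinokr
Title: Direction Tuning of Retinal Ganglion Cells and Prediction of the
    Vertical Optokinetic Reflex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the direction tuning of ON direction-selective
    retinal ganglion cells (oDSGCs) to vertical optokinetic reflex (OKR)
    behavior. Implements circular direction-tuning statistics (preferred
    direction, direction selectivity index, linear and normalized tuning-curve
    areas, Von Mises fits), a parallel-conductance leaky integrate-and-fire
    model with excitatory/inhibitory gain sweeps and spike-threshold
    calibration, pupil-landmark to angular eye-position conversion with
    saccade detection and slow-phase gain estimation, bootstrap and
    instantaneous-subtraction predictions of OKR from retinal output with an
    empirical sigmoid nonlinearity, and simulation of retinal mosaics with
    density recovery profiles. A synthetic-data module generates stimulus
    waveforms, oDSGC populations, conductance sets, population firing rates,
    and eye traces with configurable effect structure so every stage of the
    pipeline can be exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
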