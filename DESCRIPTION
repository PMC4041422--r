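Package: irekin
Title: Stopped-Flow Kinetics of IRE-RNA Binding to IRP1 and eIF4F
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of rapid-mixing (stopped-flow) kinetics for
    iron-responsive-element (IRE) RNA binding to the repressor IRP1 and the
    translation-initiation complex eIF4F. Implements the one-step bimolecular
    mass-action binding model, single- and double-exponential relaxation fits
    with F-test model selection, observed-rate (k_obs) versus concentration
    regression to recover association (k_on) and dissociation (k_off) rate
    constants, dilution (relaxation) estimates of k_off, metal-ion (Mn2+)
    condition tables with fold changes, complex lifetimes, and the kinetic and
    equilibrium partition of IRE-RNA between two competing proteins. A
    synthetic-data generator emulates the instrument (1-ms dead time, 1000
    points per shot, shot averaging) and the published experimental designs so
    the whole pipeline is testable without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
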