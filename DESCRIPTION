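Package: ocupkpd
Title: Release Kinetics, Ocular Pharmacokinetics and MIC-Anchored Dosing
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating sustained-release ophthalmic formulations.
    Fits the classical drug-release kinetics models (first order, Higuchi,
    Baker-Lonsdale, Korsmeyer-Peppas, Hixson-Crowell) to cumulative in vitro
    release data, ranks them by coefficient of determination and classifies
    the release mechanism from the Korsmeyer-Peppas exponent. Estimates
    one-compartment open-model (Bateman) pharmacokinetic parameters from
    sparse destructive-sampling aqueous-humor concentration data, including
    terminal log-linear elimination slopes and curve reconstruction from
    published summary parameters. Computes non-compartmental quantities
    (linear trapezoidal AUC with extrapolation to infinity, relative
    bioavailability), MIC-anchored PK/PD indices (Cmax/MIC, AUC/MIC, time
    and AUC above MIC) and a threshold-based dosing interval, and simulates
    repeated ocular instillation by the principle of superposition. A seeded
    synthetic-data generator emulates destructive sampling and biphasic
    burst-release profiles so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
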