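Package: acrdyn
Title: Population Dynamics and Assay Statistics for Anti-CRISPR Phages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental model of phage-bacteria population dynamics in
    which initially sensitive hosts evolve CRISPR-based resistance and
    anti-CRISPR (Acr) phages can immunosuppress resistant cells. Provides
    an ODE simulator with serial-transfer events, experiment presets and
    parameter sweeps over the Acr strength parameters (lysis probability
    phi and immunosuppression duration 1/gamma), the measurement formulas
    used in competition and efficiency-of-centres-of-infection (ECOI)
    assays (odds-ratio relative fitness, qPCR fractions, phi estimation),
    one-sample t-test conventions with Bonferroni thresholds, synthetic
    assay-data generators with log-normal and Poisson counting noise, and
    least-squares recovery of (phi, gamma) from noisy trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
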