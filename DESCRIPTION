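Package: ecmoflow
Title: Predict Extracorporeal Membrane Oxygenation Flow Rates and Circuit Pressures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter hydraulic model of a venovenous extracorporeal
    membrane oxygenation (ECMO) circuit. Fits quadratic pressure-flow
    characteristics to catalog data for cannulas, tubing, oxygenators and
    centrifugal pumps; solves the circuit/pump operating point in closed form;
    walks node pressures around the loop from the central venous pressure to
    obtain the pre-pump (P1), pre-oxygenator (P2) and post-oxygenator (P3)
    taps; and applies the hydrostatic bed-height correction. Includes
    predicted-versus-measured validation statistics (R-squared, RMSD, bias,
    relative error, observed-on-predicted regression), a factorial sweep
    driver, a synthetic bench-measurement generator for end-to-end testing,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
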