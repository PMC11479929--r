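Package: racpbpk
Title: Hybrid Physiologically Based Pharmacokinetic Modelling of
    Ractopamine Residues in Goats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK)
    model for the beta-adrenoceptor agonist ractopamine in goats, with
    flow-limited organs (liver, spleen, kidney, heart, lung) and
    membrane-limited tissues (muscle, fat, brain, remaining tissue),
    first-order oral absorption with gastric emptying and fecal loss,
    linear hepatic and renal clearance, and mass-conserving dosing
    events.  Includes stiff ODE simulation of single and repeated oral
    or intravenous regimens, WinNonlin-style non-compartmental analysis
    (lambda-z, AUC, AUMC, MRT, clearance, volumes, bioavailability),
    bounded nonlinear least-squares parameter estimation against
    multi-matrix residue data, local sensitivity analysis with
    normalized sensitivity coefficients, Monte Carlo population
    simulation with nonparametric 95/95 tolerance bounds for
    withdrawal-time estimation against maximum residue limits, and a
    synthetic residue-data generator for testing and validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
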