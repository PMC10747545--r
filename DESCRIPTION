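Package: cirrhPBPK
Title: Whole-Body PBPK Simulation of Ondansetron Exposure in Liver Cirrhosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates a whole-body physiologically based
    pharmacokinetic (PBPK) model of ondansetron in healthy adults and in
    Child-Pugh A/B/C liver-cirrhosis populations after intravenous and oral
    dosing. Tissue-to-plasma partition coefficients follow the Poulin-Theil
    tissue-composition method, hepatic elimination follows the well-stirred
    liver model with CYP1A2/CYP3A4 intrinsic clearances, and cirrhotic
    physiologies are derived from a reference adult by published Child-Pugh
    scaling factors. Includes virtual-population simulation with prediction
    envelopes, noncompartmental analysis (AUC, Cmax, half-life, clearance),
    model-qualification statistics (observed/predicted ratios, average fold
    error, RMSE, twofold criterion), exposure-increase summaries, and
    exposure-matched dose adjustment for cirrhosis, together with a synthetic
    clinical-profile generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, deSolve
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
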