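Package: mtxrenal
Title: Risk Assessment of Low-Dose Methotrexate in Renal Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combined pharmacovigilance and pharmacokinetic risk assessment of
    weekly low-dose methotrexate (<= 20 mg) in patients with impaired renal
    function. Provides disproportionality signal detection (proportional
    reporting ratio, reporting odds ratio, and Bayesian confidence propagation
    neural network information component) on spontaneous-report tables in the
    FAERS ASCII dialect; a restricted cubic spline model of the dose to peak
    plasma concentration relationship; a minimal mechanistic pharmacokinetic
    model of oral methotrexate with glomerular filtration and
    transporter-mediated tubular secretion scaled across chronic kidney
    disease stages under the intact nephron hypothesis; peak-concentration
    risk thresholds and tablet-quantized dose optimization per CKD stage; and
    seeded synthetic-data generators so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
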