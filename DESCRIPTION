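Package: contrastflow
Title: Personalised Contrast-Media Injection Protocols for Coronary CT
    Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes individualised iodinated contrast-media injection
    protocols for coronary CT angiography. Patient blood volume is
    estimated with the sex-specific Nadler formulas and combined with the
    selected tube voltage through a calibrated first-pass attenuation
    model to obtain a personalised flow rate, bolus volumes, iodine
    delivery rate and total iodine load. Includes a synthetic-cohort
    simulator (bivariate-normal anthropometrics, truncated-normal heart
    rate, tube-voltage-selection emulator) for protocol-table studies
    without patient data, and objective image-quality utilities
    (attenuation, noise, CNR, SNR, AHA 17-segment bookkeeping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
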