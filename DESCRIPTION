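Package: nalpbpk
Title: Mechanistic Pharmacokinetics of Oral Nalbuphine and Its Metabolites
    with Enterohepatic Recirculation
Version: 0.1.0
Authors@R:
    person("nalpbpk", "developers", email = "nalpbpk@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits the disposition of oral extended-release
    nalbuphine and its four major circulating metabolites (M1, M3, M4, M5)
    in healthy subjects and in moderate and severe hepatic impairment. The
    model couples a continuous (convection-diffusion-reaction) intestinal
    absorption tube to a well-stirred liver with metabolic partitioning,
    meal-triggered gallbladder emptying with beta-glucuronidase-mediated
    recycling of biliary glucuronides, and linear compartmental systemic
    disposition. Includes the well-stirred clearance arithmetic used to
    parameterize hepatic impairment, non-compartmental summary metrics
    (trapezoidal and model-integrated AUC, interval half-lives, dose
    normalization, naive pooling), stepwise parameter estimation on pooled
    concentration-time data, and a synthetic-cohort generator with
    lognormal inter-subject variability and LLOQ censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
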