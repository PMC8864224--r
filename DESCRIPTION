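Package: psmce
Title: Partitioned-Survival Cost-Effectiveness Modelling for First-Line
    Therapy in Unresectable Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead)
    partitioned-survival cohort model for cost-effectiveness analysis of
    sintilimab plus bevacizumab biosimilar versus sorafenib in unresectable
    hepatocellular carcinoma, from the Chinese healthcare system perspective.
    Provides parametric survival curves (exponential, Weibull, log-normal,
    log-logistic, Gompertz, generalized gamma) with right-censored maximum
    likelihood fitting and AIC-based family selection, hazard-ratio derived
    counterfactual curves, a discounted 21-day-cycle cohort trace with drug,
    monitoring, adverse-event, subsequent-therapy and supportive-care cost
    accounting, incremental cost-effectiveness computation, one-way
    (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic Kaplan-Meier
    generator emulating curve digitization for validating the fitting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    flexsurv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
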