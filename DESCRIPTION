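Package: occrelapse
Title: Receptor-Occupancy Trajectories and Relapse Survival Analysis for
    Antipsychotic Discontinuation Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models striatal dopamine D2 receptor occupancy over time for
    oral, 1-monthly and 3-monthly long-acting injectable paliperidone
    formulations from an Emax dose-response relation and first-order
    pharmacokinetics, simulates individual-patient placebo-controlled
    discontinuation trials whose relapse hazards are driven by the occupancy
    trajectories, and analyses the resulting survival data: per-trial Cox
    proportional hazards models with time-varying occupancy covariates, a
    case-base sampled smooth-in-time hazard model for time-varying hazard
    ratios, and DerSimonian-Laird random-effects meta-analytic pooling with
    formulation moderator tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    metafor,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
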