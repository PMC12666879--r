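Package: mstraj
Title: Disability Worsening Phenotypes and Treatment Response in Relapse-Onset Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Registry", "Modelling Group", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify disability worsening phenotypes in relapse-onset
    multiple sclerosis from longitudinal Expanded Disability Status Scale (EDSS)
    measurements, and to quantify treatment response against phenotype-specific
    expected trajectories. Includes a synthetic registry generator with known
    ground truth; confirmed-disability-worsening (CDW) event detection with
    relapse-associated worsening (RAW) versus progression independent of relapse
    activity (PIRA) classification; latent-class mixed models of EDSS versus
    time fitted by EM with information-criterion class selection; propensity-score
    matching of treated to untreated cohorts; a compiled random-forest classifier
    that transfers phenotype labels to treated patients from baseline features;
    and observed-versus-expected mixed-model contrasts including a per-patient
    disability z-score (personalized treatment response index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
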