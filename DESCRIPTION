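Package: recurmicro
Title: Recurrent-Event Survival Analysis of Gut Microbiome Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links longitudinal gut-microbiome features (amplicon sequence
    variants, co-occurrence module eigengenes, pathway abundances, alpha
    diversity) to recurrent disease-activity outcomes such as relapses and
    new MRI lesions.  Implements stratified Prentice-Williams-Petersen
    recurrent-event Cox models (total-time and gap-time clocks) with
    cluster-robust sandwich variance and proportional-hazards diagnostics,
    counting-process risk-interval construction with refractory periods and
    midpoint-imputed MRI event times, representative rarefaction,
    prevalence-based dichotomization, UniFrac/PERMANOVA community analysis,
    topological-overlap co-occurrence modules with eigengene merging,
    Benjamini-Hochberg FDR reporting, and a synthetic-cohort generator with
    planted proportional-hazards effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    picante,
    survival,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
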