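Package: npccea
Title: Markov Cohort Cost-Effectiveness Model for First-Line
    Immunochemotherapy in Recurrent or Metastatic Nasopharyngeal Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-state (progression-free, progressed, dead) Markov cohort
    model comparing first-line tislelizumab plus gemcitabine-cisplatin
    chemotherapy against chemotherapy alone in recurrent or metastatic
    nasopharyngeal carcinoma, from the Chinese healthcare payer perspective.
    Provides parametric survival curves (exponential, Weibull, log-logistic,
    Gompertz, log-normal) with right-censored maximum-likelihood fitting and
    AIC/BIC family selection, conversion of fitted curves into per-cycle
    transition probabilities, discounted cost/life-year/QALY accrual,
    incremental cost-effectiveness statistics (ICER, INHB, net monetary
    benefit), one-way and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, hazard-ratio-based subgroup
    analysis, an insurance co-payment scenario, and a synthetic pseudo
    individual-patient-data generator emulating reconstruction of survival
    times from published Kaplan-Meier curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    flexsurv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
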