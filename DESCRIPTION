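Package: otrisk
Title: Imposex Indices and Probabilistic Organotin Risk Assessment for
    Gastropod Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marine biomonitoring surveys that use neogastropods
    (e.g. the rock shell Reishia clavigera) as sentinels of organotin
    pollution. Computes individual- and site-level imposex indices (VDSI,
    RPSI, percentage imposex and sterile females, condition index),
    summarises six-analyte butyltin/phenyltin tissue panels (totals,
    composition, degradation indices, left-censoring substitution, dry- to
    wet-weight tin-equivalent conversion), fits log-logistic and Pareto
    species sensitivity distributions to measured tissue concentrations and
    literature no-effect tissue residues, and estimates the probability
    that a population is at risk, P(RQ >= 1), by Monte-Carlo simulation of
    the risk quotient. Includes the paired trend tests and rank-correlation
    analyses used in long-term imposex monitoring, a seeded synthetic-data
    generator for end-to-end testing, and a packaged site-level table of
    published Hong Kong survey indices (2004-06, 2010, 2015).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
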