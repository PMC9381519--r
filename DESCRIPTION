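Package: slaml
Title: Stage-of-Leukemia-Arrest Immunophenotypic Classification of AML
Version: 0.1.0
Authors@R:
    person("slaml", "maintainers", email = "maintainers@slaml.dev", role = c("aut", "cre"))
Description: Tools for the flow-cytometry-based stage-of-leukemia-arrest (SLA)
    stratification of acute myeloid leukemia. Provides a synthetic event-level
    and cohort-level cytometry simulator, a CD45-dim blast gate and
    percent-positive marker quantification (including CD34+CD38-CD123+
    leukemic stem cell fractions), the six-category rule-based SLA classifier
    built on CD34, CD117, CD13, CD33, cytoplasmic MPO and HLA-DR, one-vs-rest
    genotype association screens (relative risk and Fisher exact tests),
    secondary-AML labeling, functional mutation-module tallies, and survival
    analysis per SLA (Kaplan-Meier, log-rank, cumulative incidence of relapse
    with death as a competing event), together with an end-to-end pipeline
    and command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
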