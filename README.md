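# slaml — stage-of-leukemia-arrest classification of AML

Acute myeloid leukemia (AML) blasts are blocked at a specific stage of
myeloid differentiation, and that stage is readable on the day of diagnosis
from six routine flow-cytometry markers: **CD34, CD117, CD13, CD33,
cytoplasmic MPO, and HLA-DR**. `slaml` implements the resulting
*stage-of-leukemia-arrest* (SLA) stratification as a tested, reusable
pipeline for hematology biostatisticians: from event-level cytometry to a
six-category patient label, and on to the genotype-association and outcome
analyses that the label supports. Because diagnostic cytometry cohorts are
rarely shareable, the package also ships a synthetic cohort generator whose
statistical structure (SLA mixture, SLA-conditional mutation prevalences,
LSC fractions, SLA-ordered hazards) mirrors a 2,087-patient discovery
cohort, so every downstream stage is testable without any data download.

## The classifier

Percent-of-blasts values feed a fixed decision tree (a marker is "+" at
≥ 20% of blasts; cytoplasmic MPO is tiered):

```
CD34 ≥ 20%  (CD34+ AML)
 ├─ CD13 < 20 & CD33 < 20 & MPO < 10  → HSC-L   (stem-cell-like)
 ├─ MPO < 10                          → MPP-L   (multipotent-progenitor-like)
 ├─ 10 ≤ MPO ≤ 70                     → CMP-L   (common-myeloid-progenitor-like)
 └─ MPO > 70                          → GMP-L   (granulocyte–monocyte-progenitor-like)
CD34 < 20%  (CD34− AML)
 ├─ HLA-DR ≥ 20                       → MP-L    (monocyte-progenitor-like)
 └─ HLA-DR < 20                       → GP-L    (granulocyte-progenitor-like)
```

An `atypical` flag marks profiles whose secondary marker pattern (CD13/CD33
or CD117 positivity) violates the expected stage phenotype without changing
the label. Downstream, `association_screen()` computes one-vs-rest relative
risks RR = [a/(a+b)] / [c/(c+d)] with two-sided Fisher exact p-values per
(SLA, lesion); `km_estimate()`, `logrank_test()`, `cumulative_incidence()`
and `compare_cir()` cover OS/DFS and cumulative incidence of relapse with
death as a competing event (Aalen–Johansen; Fine–Gray comparison).

## Worked example

```r
library(slaml)

# one patient: percent of blasts positive per marker
p <- list(CD34 = 62, CD117 = 45, CD13 = 58, CD33 = 71, MPO = 34, "HLA-DR" = 48)
classify_sla(p)
#> <sla_label> CMP-L  [CD34+; MPO in [low, high]]

# a synthetic discovery-like cohort: mixture, mutations, outcomes
co <- simulate_cohort(cohort_config(n_patients = 1000, seed = 42))
cl <- classify_cohort(co$profiles)
cl$frequency
#>     sla   n percent
#> 1 HSC-L   6     0.6
#> 2 MPP-L 193    19.3
#> 3 CMP-L 313    31.3
#> 4 GMP-L 170    17.0
#> 5  GP-L  57     5.7
#> 6  MP-L 261    26.1
mean(cl$labels$label == co$profiles$true_sla)   # label recovery
#> [1] 0.999

# NPM1 marks the two CD34-negative (mature-arrest) stages
scr <- association_screen(cl$labels$label, co$genotypes)
subset(scr$results, lesion == "NPM1" & sla %in% c("GP-L", "MP-L"))
#>  sla lesion   a  b   c   d       rr            p
#> GP-L   NPM1  49  8 244 699 3.322332 5.699894e-20
#> MP-L   NPM1 174 87 119 620 4.140056 1.139864e-50

# survival ordered by maturity of the arrest
lr <- logrank_test(co$outcomes$os_months, co$outcomes$os_event, cl$labels$label)
#> chisq 127.5 on 5 df, p = 8.2e-26
```

The frequencies track the configured mixture (0.9 / 21.9 / 30.2 / 17.2 /
5.7 / 24.1 percent) up to multinomial noise at n = 1000; NPM1 relative risk
is far above 1 only in the CD34− stages, as configured from the printed
mutated/tested prevalences; the log-rank test sees the configured
immature-worse hazard ordering.

## Command line

```sh
inst/cli/sla simulate --n 500 --seed 7 --out cohort/
inst/cli/sla classify --profiles cohort/profiles.csv --out labels.csv
inst/cli/sla assoc    --profiles cohort/profiles.csv --genotypes cohort/genotypes.csv --out volcano.csv
inst/cli/sla survival --outcomes cohort/outcomes.csv --labels labels.csv --out curves.csv
inst/cli/sla run      --config run.json --out report/
```

All tabular I/O is CSV with documented headers; run configs are JSON
(`seed`, `simulate {n_patients, jitter_sd, events_per_specimen, seed}`,
`inputs {profiles, genotypes, outcomes}`, `analyses`).

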