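---
title: "Stages of leukemia arrest: model, synthetic world, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stages of leukemia arrest: model, synthetic world, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slaml)
```

## The model

Normal myelopoiesis passes through immunophenotypically distinct stages —
hematopoietic stem cell (HSC), multipotent progenitor (MPP), common myeloid
progenitor (CMP), granulocyte–monocyte progenitor (GMP), and finally
granulocyte (GP) or monocyte (MP) progenitors. AML blasts preserve the
marker physiognomy of the stage at which their differentiation is blocked.
`slaml` operationalizes this as a deterministic decision tree over six
percent-of-blasts values (CD34, CD117, CD13, CD33, cytoplasmic MPO,
HLA-DR), assigning each patient one *stage of leukemia arrest* (SLA):
HSC-L, MPP-L, CMP-L, GMP-L, GP-L or MP-L.

The tree's logic reflects the normal expression program: CD34 separates
immature (CD34+) from mature (CD34−) arrest; within CD34+ disease,
cytoplasmic MPO rises monotonically with maturation and is consumed in
three tiers (< 10%, 10–70%, > 70%); within CD34− disease, HLA-DR separates
monocytic (HLA-DR+) from granulocytic (HLA-DR−) arrest. CD13/CD33
negativity *together with* absent MPO distinguishes HSC-L from MPP-L,
because specific myeloid surface markers become detectable from the MPP
stage onward.

### Assumptions

* The leukemic bulk is dominated by one arrested clone; mixtures of clones
  arrested at different stages are not modelled (no soft assignments).
* Percent-positive values are taken at face value; the classifier is
  invariant to any strictly increasing transformation of raw intensities
  (it never sees intensities), which the tests verify.
* Erythroid/megakaryoblastic disease carries no dedicated markers in this
  panel and is classified by the same rules; users may carry a FAB
  annotation alongside if they need to flag those cases.

### Tunable parameters (`classifier_params()`)

| parameter | default | unit | why |
|---|---|---|---|
| `positivity` | 20 | % of blasts | clinical "+" convention (≥ 20%) |
| `mpo_low` | 10 | % of blasts | HSC/MPP-L vs CMP-L MPO tier bound |
| `mpo_high` | 70 | % of blasts | CMP-L vs GMP-L MPO tier bound |
| `hladr_split` | 20 | % of blasts | MP-L (≥) vs GP-L (<) |

Two genuinely open design points were settled as follows and are encoded in
the tests:

* **HLA-DR orientation.** Descriptions of the HLA-DR rule conflict across
  sources (figure caption vs body text). We follow the orientation
  *MP-L = HLA-DR ≥ 20%, GP-L = HLA-DR < 20%*, which matches the monocytic
  biology (monocyte lineage is HLA-DR positive) and the explicit threshold
  phrasing; the contrary caption is treated as a label swap.
* **Boundary ties.** MPO exactly 10 or exactly 70 → CMP-L; positivity uses
  `≥` (a profile at exactly 20% is "+"). At the event level, intensity
  strictly greater than the cutoff counts positive, so an event exactly at
  the cutoff is negative. These conventions make results bit-reproducible.
* **CMP-L and CD13/CD33.** The MPO tier alone assigns CMP-L; a CD34+
  profile in myeloid MPO range with both CD13 < 20% and CD33 < 20% keeps
  its label but is flagged `atypical`, as is CD117 < 20% in any CD34+
  profile. The flag separates rule-consistent from phenotypically odd
  profiles without inventing a seventh class.

## Gating

Event-level input is reduced by a rectangular blast gate in (CD45, SSC):
CD45-dim (default 20–700 arbitrary units, i.e. above the unstained floor
and below the bright lymphocyte mode) and SSC low/intermediate (default
0–1200, covering the simulated blast SSC distribution to ~4 sigma).
Clinical gates are hand-drawn polygons; a parametric rectangle is
reproducible and sufficient for synthetic data. A specimen retaining fewer
than 10,000 gated events carries a `low_count` flag (acquisition targets at
least 10^4 blasts). Positivity cutoffs are either fixed intensities
(default 150, which separates the two synthetic intensity components) or
derived per marker as the 99.5th percentile of a supplied negative-control
population (`positivity_cutoffs()`); both modes exist because event-level
cutoffs are a laboratory convention, not part of the published rule set.

The leukemic stem cell (LSC) compartment is quantified as the percentage of
gated blasts that are CD34+ and CD123+ but CD38−.

## The synthetic world

`simulate_events()` and `simulate_cohort()` generate the *stated world* the
analyses assume; their defaults are fixed by published summary statistics
and are not dials:

* **SLA mixture** — 18 / 458 / 630 / 360 / 119 / 502 of 2,087
  (0.9 / 21.9 / 30.2 / 17.2 / 5.7 / 24.1 percent).
* **Mutation prevalences** — P(lesion | SLA) point estimates from the
  printed per-SLA mutated/tested counts for CEBPA, DNMT3A, FLT3-ITD,
  FLT3-TKD, IDH1, IDH2 and NPM1 (`inst/extdata/discovery_mutations.csv`), drawn
  independently per lesion given the SLA (marginals only are published; a
  pairwise co-mutation structure can be layered on by editing the table).
* **LSC fractions** — 18.03% (HSC/MPP-L), 11.54% (CMP-L), 7.83% (GMP-L),
  0.5% (GP/MP-L).
* **CR probabilities** — 72 / 72 / 76 / 87 / 79 / 85 percent in
  HSC-L…MP-L order.

Where the sources publish no value, one realistic choice was made and
frozen:

* **Intensity model.** Two log-normal components per marker (negative:
  median 50, positive: median 500, both sdlog 0.4). Only percent-positive
  is published; any two-component model reproducing a target
  percent-positive would do, and the parameterization is exposed on the
  archetype.
* **Marker jitter.** Logit-normal jitter around the archetype percentages,
  default sd 0.3 on the logit scale (≈ ±8–10 percentage points in
  mid-range) — large enough to produce occasional borderline profiles
  (~0.05% cross a decision boundary), small enough that the archetypes
  remain identifiable. At sd 0 profiles equal the archetype exactly.
* **CD38 convention.** Non-LSC blasts are CD38+ (the archetype's CD38
  fraction defaults to 1 − LSC fraction), so the CD34+CD38−CD123+ gate
  recovers exactly the configured LSC fraction up to binomial noise.
* **Outcome model.** Exponential hazards per (SLA, event type) with
  independent uniform censoring on (0, 120) months: OS hazards
  0.050/0.045/0.035/0.012/0.018/0.020 per month (median OS ≈ 14–58 months,
  ordered immature-worse), relapse hazards 0.060/0.055/0.045/0.015/0.022/
  0.025, death-in-CR hazard 0.010 everywhere. No parametric outcome model
  is published; the simplest competing-risks generator that reproduces the
  qualitative ordering is used. Patients never achieving CR contribute to
  OS only.
* **Contamination.** 10% CD45-bright lymphocyte-like events per specimen by
  default, so the blast gate does real work.

All draws flow from one integer seed; identical configuration implies a
byte-identical cohort.

### What a green test does not establish

The generator emulates marginal structure: mixture proportions, per-SLA
prevalences, hazard ordering. It does **not** emulate co-mutation
dependence, subclonal mixtures, instrument drift, spectral spillover,
hand-drawn gate variability, or covariate-dependent censoring. Recovery
tests therefore certify the pipeline's arithmetic and its behaviour under
the assumed world, not clinical performance on real cytometry.

## Statistical conventions

* **Relative risk** is one-vs-rest — prevalence inside the SLA over
  prevalence in all other SLA pooled, tested patients only — with the
  Haldane–Anscombe +0.5 correction applied to all four cells (and flagged)
  whenever a cell is zero. Raw two-sided Fisher exact p-values are
  reported by default (matching the original screens); Benjamini–Hochberg
  is available behind `adjust = TRUE`.
* **Fisher's exact test** uses the point-probability two-sided rule: the
  sum of hypergeometric probabilities not exceeding that of the observed
  table (with a 1e-7 relative tolerance against floating-point ties). The
  test suite proves equality with full enumeration for all margins ≤ 12.
* **Kaplan–Meier** is the standard product-limit with Greenwood variance;
  at tied times events precede censorings. OS runs from diagnosis, DFS and
  relapse from complete remission; patients dying before CR never enter
  DFS/CIR.
* **Cumulative incidence** is Aalen–Johansen with death-without-relapse as
  the competing event; the conservation identity
  CI_relapse + CI_death + event-free = 1 holds at every step to 1e-9.
  Group comparison (`compare_cir()`) is the Fine–Gray construction
  (`survival::finegray` + Cox Wald test), the named delegated contract;
  Gray's test is its score analogue.
* **Quantiles and rounding.** Medians/IQRs use type-7 linear interpolation.
  Percentages are carried at full precision and rounded only for display:
  one decimal, half away from zero (RR: two decimals).

## Known limitations

* The classifier is hard: a profile at 19.9% CD34 and one at 20.1% land in
  different branches. The `atypical` flag and the jitter generator exist to
  surface, not hide, this brittleness.
* Simulated specimens share one intensity model across markers; real
  cytoplasmic MPO staining behaves differently from surface stains.
* Direction recovery for association screens is power-limited in the
  HSC-L stratum (0.9% of patients): lesions whose enrichment is only
  borderline (prevalence ratio just above 2) in that stratum cannot be
  recovered reliably at cohort sizes of ~2,000, and the acceptance suite
  documents exactly that.
* FCS binary parsing is out of scope here; event-level input is tabular
  CSV with a channel→marker map (`read_event_csv()`), which any FCS reader
  can produce.
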