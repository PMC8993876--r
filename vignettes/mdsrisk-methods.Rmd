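---
title: "Risk scoring and survival methods in mdsrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk scoring and survival methods in mdsrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsrisk)
```

## The problem

Myelodysplastic syndromes (MDS) are clonal hematopoietic stem-cell
disorders with cytopenias, marrow dysplasia and a substantial risk of
progression to acute myeloid leukemia. Treatment intensity is decided by
prognostic scores, most commonly the Revised International Prognostic
Scoring System (IPSS-R), which combines cytogenetics, marrow blast
percentage and blood counts but ignores somatic mutations. `mdsrisk`
implements a full prognostication workflow for MDS cohort tables — ISCN
karyotype parsing, IPSS-R, a mutation-augmented "M-IPSS-R" score,
mutation association tests and survival modelling — together with a
seeded synthetic cohort generator so that every stage can be exercised
and property-tested without access to patient-level data.

## Cytogenetic classification

`parse_iscn()` supports the ISCN subset seen in conventional MDS
karyotyping: mosaic clones separated by `/` with bracketed cell counts,
numerical gains and losses (`+8`, `-7`, `-Y`), and the structural tokens
`del`, `add`, `inv`, `t`, `i`, `dup`, `der` and `mar`, with `idem`
expanding the stem clone. Ring chromosomes, insertions and nested
rearrangements are rejected with an error naming the token — a silent
best-effort parse would corrupt the downstream abnormality count on
which the complex-karyotype rules depend.

Abnormality identity is the normalized arm-level token: `del(5)(q13q33)`
and `del(5)(q13q34)` are the same `del(5q)` lesion, and the same token
appearing in two subclones counts once (union across clones). Marker and
derivative chromosomes count one abnormality each toward complexity.

Risk assignment is data-driven: `load_cyto_rules()` reads a JSON rule
table applied in precedence order (very complex >3 abnormalities, then
complex with exactly 3, then the specific poor lesions such as monosomy 7
and 3q aberrations, then the named single/double categories, with any
residual single or double falling to Intermediate). The shipped default
encodes the IPSS-R comprehensive categories; an alternative
classification can be swapped in without a code change. Isolated `-Y`
and `del(11q)` are VeryGood under that table; because many published
cohort tables report only four cytogenetic rows, the cohort-level
classifier also emits a `group4` column in which VeryGood is merged into
Good (a config flag, `collapse_very_good`).

Patients with an absent karyotype are an explicit decision, never a
silent default: strict mode refuses them with the patient ids named,
and the permissive mode records `missing-karyotype:normal-assumed` in
the `rule_fired` audit column.

## IPSS-R and the 3.5-point dichotomy

`score_ipssr()` sums five components (cytogenetics 0–4, blasts ≤2 → 0,
>2–<5 → 1, 5–10 → 2, >10 → 3, hemoglobin ≥10 → 0, 8–<10 → 1, <8 → 1.5,
platelets ≥100 → 0, 50–<100 → 0.5, <50 → 1, ANC ≥0.8 → 0, <0.8 → 0.5;
all in their conventional units of g/dL, ×10⁹/L and percent). Totals are
multiples of 0.5 in [0, 10] and map to the five tiers at cutpoints
1.5/3/4.5/6. The four-group collapse (VeryLow merged into Low) mirrors
how many cohort studies tabulate IPSS-R, and `dichotomize_ipssr()`
implements the lower/higher split at ≤3.5 versus >3.5 points used to
define lower-risk MDS.

The component bins live in `inst/extdata/config/ipssr_default.json`.
Bins are validated at load: they must tile the factor's domain exactly,
and overlapping or gapped bins are rejected. This makes the score table
a replaceable artifact — a misremembered cutpoint is a one-line JSON
edit, not a code patch.

## The M-IPSS-R score

The mutation-augmented score sums four factors:

| factor | 0 | 0.5 | 1 | 2 | 3 | 4 | 5 |
|---|---|---|---|---|---|---|---|
| selected-gene mutations | 0 | | 1 | 2 | 3 | 4 | >4 |
| marrow morphology | SLD | | MLD | 5–10% blasts | >10% blasts | | |
| cytogenetics | Good | | Intermediate | Poor | VeryPoor | | |
| age (years) | ≤30 | 31–50 | 51–60 | >60 | | | |

with selected genes TET2, ASXL1, TP53, RUNX1, NRAS, KRAS and NOTCH1.
Tiers are Low (total ≤ 3), Intermediate (3.5–5.5) and High (> 5.5).
Several points here were genuinely open and are decided as follows:

* **The total is the sum of the four factors only**, not the four
  factors added on top of the IPSS-R hematologic points: the scoring
  table lists exactly four prognostic variables, and only this reading
  keeps the published tier band (1.5–3 Low) reachable by typical
  lower-risk patients. An additive-to-IPSS-R variant can be expressed by
  editing the score-table JSON if a user wants it.
* **Totals below 1.5 are classified Low.** The published Low band starts
  at 1.5 and leaves smaller totals (possible for a young SLD patient
  with good cytogenetics and no mutations) undefined; mapping them to
  Low is the only monotone completion.
* **Mutation counting is per distinct selected gene** after gene-family
  pooling (JAK2/JAK3 → "JAK2/3", IDH1/IDH2 → "IDH1/2"): two TP53 calls
  are one mutated gene. The pooling map is config
  (`gene_pooling_default.json`), not code.
* **Morphology scoring for patients with excess blasts uses the blast
  bins** (5–10% → 2, >10% → 3); SLD/MLD patients below 5% blasts score
  their dysplasia bin, so an MLD patient with 4% blasts scores 1. An EB
  patient recorded with blasts under 5% (a morphologic call the blast
  count does not support — the reader warns about these) still scores
  the lowest blast bin.
* The shipped table is versioned `reconstructed-v1` and every score
  breakdown records the version it used.

`compare_stratification()` aligns the IPSS-R four-group scale with the
three M-IPSS-R tiers (VeryHigh aligns with High, the top level of the
shorter scale) and reports per-patient direction plus counts and
fractions to one decimal, always disclosing its denominator.

## Association statistics

The test policy is explicit: **Fisher's exact test for 2×2 tables and
Pearson's χ² without continuity correction for r×2 tables**. The
two-sided Fisher p-value is the point-probability (minimum-likelihood)
sum over the hypergeometric support with fixed margins — the test suite
checks it against full enumeration for every 2×2 table with grand total
up to 40. χ² is uncorrected because the Yates correction changes the
4×2 cytogenetic-table p materially and no correction is the convention
for r×c tables of this size.

Two numerical caveats are worth knowing. First, the point-probability
two-sided Fisher p and the χ² p can differ by several hundredths in the
mid-range even when all expected counts exceed 10; they agree closely
only in the significance region, and the package's sanity tests are
written accordingly. Second, `association_screen()` reports degenerate
tables (a gene absent from the cohort, or mutated in everyone) with
p = 1 and a flag rather than an error, because a screen over a gene list
should not abort on an empty row. No multiplicity adjustment is applied
by default, matching common single-study practice; a Benjamini–Hochberg
option exists for reuse.

The frequency-table population is selectable: `denominator =
"mutated_only"` reproduces per-gene frequency tables computed among
mutated patients, while `"all"` uses the whole cohort (the convention
for mutation-incidence tables).

## Survival analysis

`km_estimate()` is the product-limit estimator; the median is the
smallest time at which survival reaches 0.5 or below, reported as
not-reached when the curve never gets there. `km_by_factor()` adds the
log-rank test and a poor-survival flag for groups whose median OS is
below 25 months.

Cox models (`cox_univariate()`, `cox_multivariate()`) are
partial-likelihood fits with **Efron tie handling** — survival recorded
in whole or tenth months produces many ties, and Efron is the less
biased standard choice (Breslow is available by argument). Three-level
factors (morphology SLD<MLD<EB; cytogenetics Good<Intermediate<
Poor-or-VeryPoor) enter as a **single ordinal 0/1/2 covariate** by
default: cohort studies that report one hazard ratio per such factor can
only have fit a single trend coefficient. Dummy coding is available by
argument for users who want per-level contrasts. Wald 95% intervals are
exp(β ± 1.96·SE). A constant covariate is an "inestimable" error; exact
collinearity is an error naming the pair; complete separation is flagged
as non-convergence (detected through exploded standard errors) rather
than silently reported. Patients missing OS or the event flag are
excluded from survival operations with a logged count but retained for
scoring and association work.

## The synthetic cohort generator

`generate_cohort()` emulates a 152-patient MDS study population:

* ages from a discretized triangular distribution on [16, 90] with mode
  57.1, giving median 55 (the triangular shape is an assumption — only
  the median and range are constrained by the emulated cohort);
* sex 83:69 male:female; morphology SLD:MLD:EB at 45:50:46;
* cytogenetic categories at 0.816/0.105/0.053/0.026 over
  Good/Intermediate/Poor/VeryPoor, with ISCN strings synthesized to
  classify back to the drawn category (26.6% of Good karyotypes carry an
  isolated good-risk deletion so that roughly 40% of the cohort is
  chromosomally abnormal);
* independent per-gene Bernoulli mutations with prevalences from the
  emulated frequency table (no joint distribution is available to
  emulate, so co-occurrence is independent by default);
* variant classes drawn at 159:21:12:10 over
  substitution/deletion/insertion/duplication;
* survival from a proportional-hazards model: exponential baseline
  scaled by exp(linear predictor) over age ≥60 (HR 1.885), morphology
  ordinal (1.852), cytogenetics ordinal (1.675) and the seven selected
  genes (TET2 1.821, ASXL1 2.556, TP53 6.290, RUNX1 2.376, NRAS 3.403,
  KRAS 3.697, NOTCH1 2.507), administratively censored at 120 months
  with a 15% uniform-dropout fraction. The blast-percentage and IPSS-R
  effects are not added as separate multiplicative factors: both are
  deterministic functions of fields already simulated, and stacking
  their marginal hazard ratios on top of morphology and cytogenetics
  would double-count risk.

The baseline rate (0.0008 events per patient-month) was calibrated once
so that about 35% of patients die before censoring, and is config like
everything else. Ground truth — true coefficients, realized linear
predictors, censoring times — is returned as a sidecar (and written to
`truth.json` by the pipeline) so recovery tests can use it while the
analysis path physically cannot.

What passing tests on synthetic cohorts do **not** show: the generator
has no mutation co-occurrence structure, no association between
mutations and cytogenetics or blasts (beyond what the survival model
induces), exact proportional hazards, and exponential baseline — real
cohorts violate all four. Tests against it validate the machinery
(scoring arithmetic, test statistics, estimator consistency), not
clinical effect sizes.

## Problem sizes and numerical choices

The test suite uses two-arm cohorts of n = 3000 for hazard-ratio
recovery (log-HR relative error under 15% for planted ratios 0.5, 2 and
6.29 with 20% dropout), 100 replicates of n = 2000 for null CI coverage,
200 replicates of the default 152-patient cohort for the marginal
emulation checks, and the exhaustive Fisher enumeration up to grand
total 40 — sizes at which the checked properties are sharp while a
full run stays in the couple-of-minutes range. Cox fits iterate to the
survival package's defaults (relative log-likelihood tolerance well
below 1e-9, capped iterations) and p-values are kept at full precision
internally; rounding to 3 decimals happens only in report formatting.

## Limitations

* The ISCN subset excludes composite karyotypes, rings, insertions and
  nested derivatives; cohorts containing them need manual curation.
* Nonsynonymous/damaging variant filtering is assumed done upstream; the
  mutation reader accepts what it is given.
* No competing risks, time-varying covariates or AML-transformation
  endpoint; overall survival only.
* The M-IPSS-R table is a reconstruction (version `reconstructed-v1`);
  if an authoritative per-cell table becomes available it can be dropped
  in as JSON without touching code.
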