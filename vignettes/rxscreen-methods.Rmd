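---
title: "Screening prescriptions against label indications and contraindications: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening prescriptions against label indications and contraindications: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxscreen)
```

## The problem

Regulators approve a drug for specific medical conditions (its label
indications) and name conditions under which its use is expected to do more
harm than good (drug–disease contraindications). In household survey
microdata of the US non-institutionalised population, each reported
prescription fill can be screened against the patient's recorded conditions:
was the drug taken for an approved indication (and, if not, it was off-label),
and did the patient have a condition for which the drug is contraindicated?
`rxscreen` implements that screening pipeline end to end — knowledge-base
construction, record linkage, per-prescription classification, prevalence
aggregation, and person-level regression of health status and utilisation on
use patterns — together with a synthetic-data generator that makes every
stage testable without access to licensed source extracts.

## The knowledge base

Drug–condition relations arrive as (drug, SNOMED CT concept, relation) pairs
plus a SNOMED CT → ICD-10-CM map. The map is one-to-many; a concept expands
to *all* of its ICD-10-CM targets, which maximises recall and matches the
scale of published pair counts. All disease matching is at the 3-character
ICD-10 category level (`E11.9 → E11`): survey condition files code at that
resolution, and finer matching would manufacture false off-label calls.
Concepts absent from the map are dropped, never guessed, and counted in a QC
report. Drug identity is the normalised active-ingredient name, since both
survey files and the drug resource report ingredients.

## Classification

For prescription $j$ of person $i$ with drug $d$, let $L_j$ be the ICD-10
categories of conditions explicitly linked to the event, $C_i$ all (current)
categories recorded for the person-year, and $I_d$, $K_d$ the drug's
indication and contraindication sets. The four indicators are pure set
algebra:

* `indic_narrow` $= \mathbb{1}[L_j \cap I_d \neq \emptyset]$
* `indic_broad` $= \mathbb{1}[C_i \cap I_d \neq \emptyset]$ (off-label $=$
  its complement)
* `contraindicated` $= \mathbb{1}[C_i \cap K_d \neq \emptyset]$
* `indic_not_contra` $=$ `indic_broad` $\times (1 -$ `contraindicated`$)$

Since $L_j \subseteq C_i$, narrow implies broad. Prescriptions for drugs
absent from the knowledge base are flagged out of scope and excluded from
denominators by default (the published analyses cover only linkable drugs);
`classify_all(..., out_of_scope = "offlabel")` instead counts them as
off-label for sensitivity analysis. Drugs with indication entries but no
contraindication entries get `contraindicated = 0`: absence of evidence of
harm is treated as not-contraindicated. Person condition sets default to
*current* conditions (the survey's own definition — a condition linked to an
event in the year); `current_only = FALSE` is available because it is
ambiguous whether published contraindication matching was so restricted.

Person-year exposures are unweighted means over the person's in-scope
prescriptions: `frac_indicated` (mean of `indic_broad`),
`frac_offlabel = 1 - frac_indicated`, `frac_contraindicated`, plus the
prescription count and the mean FDA approval year (one term per event, so
repeat fills count repeatedly). Survey weights are read and carried but not
used in the default tabulations, which mirror unweighted prescription
counts.

## Aggregation

`prevalence_table()` reports $100\times$ indicator means by stratum with an
overall row; the algebraic identity
$\sum_i n_i p_i / \sum_i n_i = p_{\text{overall}}$ holds exactly before
rounding and is used both as an internal invariant and to audit published
tables (`combine_prevalence_rows()`). `contra_mixture()` applies the law of
total probability to recombine contraindication rates conditional on
indication status. `median_split_compare()` splits persons at the median of
an exposure fraction — ties go to the low group, i.e. low $=$
value $\le$ median, a documented convention since "below/above the median"
leaves ties unspecified — and compares outcome means with Welch's
unequal-variance $t$ test (the published work does not state its test; Welch
is the robust default). Total expenditure is compared as
$\log(\text{expenditure}+1)$; the $+1$ keeps zero-expenditure persons in the
analysis, another rule the source tables leave unstated.

## Regression layer

The person-level models regress a health-status or utilisation outcome on
`frac_contraindicated` and `frac_indicated`, controlling for: one dummy per
3-character condition code present in the data (the analogue of "each of
477 medical conditions"), sex, one dummy per single year of age, education,
race, survey year, one dummy per distinct prescription count (capped at 30,
pooled above — nonparametric in the count without exploding the design),
and the mean FDA approval year. Three estimators share this design:

* **LPM** — OLS with HC1 heteroskedasticity-robust standard errors (the
  variance estimator is unstated in the source; robust is the conservative
  default). Rank deficiency raises an error naming the collinear columns.
* **Probit** — ML probit reporting *average marginal effects*
  $\widehat{AME}_j = \overline{\phi(x'\hat\beta)}\,\hat\beta_j$ with
  delta-method standard errors, so estimates are on the LPM scale.
  Separation triggers a warning and a ridge-penalised Newton refit flagged
  in the output.
* **DML (partially linear model)** — $Y = \theta D + g(X) + \varepsilon$ via
  $K$-fold cross-fitting: nuisances $\mathrm{E}[Y|X]$ and $\mathrm{E}[D|X]$
  are learned out-of-fold (random forest, depth-capped regression tree, or
  linear), and the partialling-out score gives
  $\hat\theta = \sum v u / \sum v^2$ with influence-function variance
  $\widehat{\mathrm{Var}} = n^{-1}\overline{\psi^2}/\overline{v^2}^2$,
  $\psi = (u - \hat\theta v)v$. Each exposure is estimated with the other
  among the controls. A fold with a constant residualised exposure forces a
  fresh fold split, with an error after three attempts. Defaults: 5 folds,
  500-tree forest, depth-8 tree, seed 20160101. With `n_folds = 1` and the
  linear learner the estimate equals partialled-out OLS exactly
  (Frisch–Waugh–Lovell), which is the package's exact oracle for the DML
  code path.

Every estimate row carries a "mean percentage": $100 \times$
estimate $\div$ outcome sample mean. That normalisation reproduces the
printed magnitudes of the published tables (e.g. an estimate of 0.0369
against an outcome mean of about 0.321 gives 11.49%), and is implemented as
such; it is an interpretation of an otherwise undefined column. Outcomes are
modelled on their natural scale except total expenditure
($\log(\cdot + 1)$). Multiple outcomes are estimated independently with no
multiplicity correction, matching the published presentation. The estimate
tables default to linear-model coefficients (the published coefficient
tables are labelled "general linear regressions"); probit AMEs and DML are
the robustness layer.

## The synthetic generator

`generator_config()` describes the emulated world: a drug universe with
Poisson-sized indication/contraindication category sets and uniform FDA
approval years; persons with Poisson condition sets over a fixed category
universe; zero-truncated-Poisson prescription counts (plus a configurable
zero-prescription share, default 15%, mirroring the roughly one-third of
survey persons with no fills who are retained but excluded from analysis).
Each prescription is drawn *indicated* with probability
`p_indicated_prescribing` — a drug indicated for one of the person's
conditions, the event link pointing at the matching condition with
probability `p_narrow_link` — and otherwise uniformly from drugs *not*
indicated for any of the person's conditions. Contraindication status is
never sampled directly; it emerges from the person's conditions meeting the
drawn drug's contraindication set, so the broad/contraindicated correlation
structure is organic (sicker persons are both more likely to find an
indicated drug and more likely to hit a contraindication, reproducing the
published pattern of a *higher* contraindication rate among indicated than
off-label prescriptions). The drug-condition layer is emitted as concept
pairs plus a one-to-many concept map and re-ingested through
`build_knowledge_base()`, so generated files exercise the real input path.

Outcomes are generated from the person's *true* exposure fractions:
binary limitation outcomes through a clipped linear-probability link
(clip $[0.01, 0.99]$) so the LPM is correctly specified and recovery tests
are sharp (a logit link is available for stress tests); log-normal
expenditure; Poisson visit counts. Per-condition effects drawn once from a
zero-mean normal enter every outcome, creating exactly the confounding the
condition-dummy block must absorb. Default effect sizes are
$\beta_{\text{contra}} = +0.04$ and $\beta_{\text{indic}} = -0.03$ on the
probability scale, the magnitude of the published ANYLMT coefficients, with
intercepts near the published outcome means.

Two presets are shipped:

* `preset_paperlike()` — tuned to the published headline rates (75%
  indicated / 54% contraindicated / 33% indicated-not-contraindicated,
  within about ±3 points at $n \ge 5000$ persons). Densities come from the
  hit-probability identity $1-(1-k/C)^m$: with a 120-category universe and
  6 conditions per person, a mean contraindication set of 16 categories
  gives a hit rate near 0.54, and `p_indicated_prescribing = 0.75` pins the
  broad rate.
* `preset_recovery()` — designed for estimator validation, not rate
  matching: ~1.6 prescriptions per person and a Beta-distributed per-person
  indicated-prescribing propensity (sd 0.25) keep enough variance in the
  exposure fractions that coefficient standard errors are near 0.015 at
  $n = 5000$, so effects of 0.03–0.04 are sign-identified in well over 95%
  of replicates. This is a power calculation done at design time; few-fill
  persons are common in real survey data, but the preset's purpose is
  statistical, and its prevalence rates are not calibrated to anything.

What the generator does *not* emulate: real drug names or therapeutic-class
compositions, demographic marginals of any actual survey, longitudinal
correlation across panel years, dose/route/age-specific label restrictions,
and drug–drug interactions (the screening is drug–disease only). Passing
tests therefore demonstrate the correctness of the algebra, the estimators
and the calibration machinery — not that any particular real-world
prevalence estimate is right.

## Numerical choices and problem sizes

* Classification is deterministic set algebra; pipeline output on generated
  data is required to equal the generator's ground truth record for record,
  with no tolerance.
* Prevalence recombination identities are asserted to $10^{-9}$ relative;
  the published-table audit uses the printed two-decimal precision, and the
  contraindication mixture identity a 0.05-point band for rounded inputs.
* The recovery study runs 100 replicates at 5000 persons for LPM/probit
  coverage and sign checks. The DML-versus-naive-OLS study runs 60
  replicates at $n = 3000$ with a 200-tree forest and five folds over a
  five-dimensional nonlinear confounding design ($\sin$ transforms entering
  both treatment and outcome) — sizes chosen to make the bias contrast and
  the coverage band informative on a single CPU.
* All randomness flows from explicit integer seeds; with seeds fixed, the
  generator's emitted files are byte-identical across runs and the DML
  estimate is bit-reproducible.
* Degenerate inputs are errors, not silent results: empty drug tables,
  malformed ICD codes, unknown identifiers, constant exposures (rank
  deficiency), all-zero binary outcomes, and median splits with fewer than
  two persons per side.

## Known limitations

The package deliberately does not implement survey-weighted population
inference (weights are carried, unused), variance strata/PSU handling,
causal identification, or parsing of the licensed upstream releases; readers
accept their documented layouts via the schema-mapping configuration, but
shipped fixtures are synthetic. Exact published population estimates (e.g.
56.5% narrow-indicated) depend on those licensed extracts and are covered
instead by the internal-consistency algebra on the printed table and by the
calibrated preset's headline rates.
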