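---
title: "Methods: rubric scoring, cascade estimation and the synthetic screening world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rubric scoring, cascade estimation and the synthetic screening world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsscreen)
```

## The screening problem

Familial chylomicronemia syndrome (FCS) is a recessive defect of the
lipoprotein lipase pathway producing sustained fasting chylomicronemia:
fasting triglycerides (TG) persistently far above 10 mmol/L, frequent
acute pancreatitis, young onset, and — unlike the far more common
multifactorial chylomicronemia (MFCS) — no secondary aggravating factors
such as diabetes, hypothyroidism, alcohol abuse or corticosteroid therapy.
At roughly one case per million, screening a hospital record system for
FCS means evaluating a clinical rubric over millions of longitudinal
records and then prioritizing the handful of survivors.

`fcsscreen` implements that pipeline: a per-patient rubric engine, a
cascading population filter, distribution/prevalence reporting, a
synthetic cohort generator with ground-truth strata, and a repeated
train/test classification benchmark with interpretable tree
introspection.

## The rubric as operationalized on records

The expert-panel score sums nine criteria; totals range from −5 to 15.
Operationalizing it on raw tables required a handful of decisions, all
surfaced in `fcs_config()`:

* **"Three consecutive blood analyses"** means three consecutive entries
  of the *date-ordered, fasting-eligible TG sequence*, each strictly
  above 10 mmol/L. Intervening non-TG labs are irrelevant and non-fasting
  TG values are excluded from the sequence rather than breaking the run:
  the criterion speaks of consecutive analyses, not calendar spacing.
* **Strict inequalities** everywhere ("> 10", "> 20", "< 2"), following
  the rubric's wording.
* **Fasting flags** are rarely recorded reliably in retrospective
  extracts; an unknown flag counts as fasting by default
  (`unknown_fasting_counts_as_fasting`), since hospital lipid panels are
  predominantly drawn fasting. The prior-low criterion (−5) deliberately
  considers *all* TG measurements, fasting or not.
* **Evaluability gate.** The absence-based criteria (+2 no secondary
  factor, +1 no familial combined hyperlipidemia) only score when the
  patient has at least one fasting-eligible TG above 10 mmol/L
  (`min_tg_records_for_absence_criteria`). Ungated, every record-poor
  patient would collect +3 vacuously, which contradicts the observed
  population distribution where scores of 3+ are at the per-mille level;
  the rapid cascade likewise applies "+2 no secondary factors" only
  after the TG filter.
* **Onset of symptoms** is not a recorded field; it is proxied by the
  earliest of (first fasting-eligible TG > 10 mmol/L, first pancreatitis
  diagnosis), with age computed in whole years from the birth year. Only
  the narrowest satisfied band scores (+3 under 10, +2 under 20, +1
  under 40) — bands are exclusive, not cumulative, keeping the rubric
  maximum at 15.
* **Treatment non-response** (+1 when TG declines less than 20% under
  hypolipidemic treatment) needs a treatment start date, which the data
  model does not carry; the criterion scores 0 unless a date is supplied
  per patient. Medians of the fasting-eligible TG before/after the date
  are compared.
* **ICD-10 prefix sets** (configurable): diabetes E10–E14, metabolic
  syndrome E8881, hypothyroidism E03, alcohol abuse F10/Z721,
  corticosteroids Z795; exemptions pregnancy (chapter O, Z32–Z37) and
  ethinylestradiol Z794; pancreatitis K85/K860/K861; abdominal pain R10
  with "recurrent" operationalized as ≥ 2 distinct dates; FCHL E782 plus
  family history Z834.
* **Classification**: total ≥ 10 "likely", 8–9 "unlikely", ≤ 7 "highly
  unlikely". The published footnote variant of the thresholds conflicts
  with the published tables' own clustering and leaves 9 ambiguous; the
  table convention is the default and the footnote variant is available
  as `classification_rule = "footnote"`.
* Negative totals are retained on score results but floored at zero in
  distribution tables, whose "0+" row must cover the whole roster.

## The rapid cascade

`run_cascade()` filters the population through the strong, objective
criteria in a fixed order — sustained TG and never below 2 (label "5+"),
no secondary factor ("7+"), peak above 20 ("8+"), onset under 40 ("9+"),
pancreatitis ("10+") — reusing the exact scoring-engine predicates, so
any divergence between cascade counts and full-rubric counts reflects
only the criteria the cascade omits (abdominal pain, FCHL, treatment
response), never divergent predicate logic. Counts are non-increasing by
construction and every stage-k survivor's full total is at least the
stage label (from stage 2 on; the "0+" stage covers negative totals the
same way the distribution tables floor them).

## Rates

Cohort tables in this field mix percent, per-mille (‰), per ten thousand
(‱), per 100,000 ("pcm") and per million ("ppm"). `prevalence_rate()`
rounds half-up at 2 decimals (1 decimal reproduces narrative-style
rates) and the `"auto"` scale picks the smallest unit at which the value
reaches 1, which reproduces the published tables' mixed usage. One known
anomaly: 275/590,500 prints as 4.67‱ in the source material but
computes to 4.66 under any half-up convention; it is documented here and
not chased.

## The synthetic world

`generate_cohort()` emulates the *structure* the analysis assumes, not
any real cohort. Three strata with per-patient Poisson visit counts
(mean 8, minimum 1) over an 8-year window, TG and total cholesterol at
every visit and the remaining panel present with probability 0.7 per
visit (missingness is deliberate — the feature builder must cope):

* **Background** (the rest): fasting TG log-normal, median 1.3 mmol/L;
  first-visit age from a truncated normal (38 ± 23, clipped to 1–90);
  low-rate secondary-factor codes (diabetes 8%, alcohol 3%, ...);
  pancreatitis 0.5%.
* **MFCS-like** (1%): TG median 8 mmol/L; at least one secondary-factor
  code always; elevated liver enzymes and glucose (GGT 60, GPT 40 U/L,
  glucose 7 mmol/L medians); with probability 0.3 one TG value below
  2 mmol/L — the −5 discriminator the rubric exploits; pancreatitis 10%.
* **Planted FCS** (testing default 0.2%; a realistic hospital fraction
  is ~2 per 100,000): at least 3 visits, the first three fasting with TG
  forced above the sustained threshold, all TG floored at 2.5 mmol/L
  ("never below 2", with margin), TG median 16 mmol/L, cholesterol
  clamped to 4–11 mmol/L, no secondary codes, first-visit age below 40
  with half below 20, pancreatitis 50%, male fraction 0.8 (vs 0.45
  elsewhere).

Log-normal laboratory distributions were chosen because lipid panels are
strictly positive and right-skewed; all location/scale parameters live
in `default_lab_params()`, not in code. The auxiliary analytes are
*synthetic assumptions*: published evidence fixes only the direction of
each stratum contrast (planted FCS sits above the decisive TG and
basophil/lymphocyte/hemoglobin cuts and below the liver-enzyme, glucose,
sodium, creatinine and inflammation cuts), so magnitudes were set once
at clinically plausible levels. One correction was made during
development: an early parameterization gave basophil percentages a
near-perfect stratum separation (~4 SD on patient means), which
contradicts the intended world where TG aggregates dominate every
feature ranking and basophils are a weak auxiliary signal; the planted
shift is now mild (0.55% vs 0.4% medians at sdlog 0.45).

`planted_score_floor()` returns the rubric points the construction makes
deterministic — +5 sustained, +2 no secondary factor, +1 onset under 40
(8 with defaults; 9/10 when pancreatitis or narrow onset is forced). The
floor is conservative: planted FCS patients also carry no FCHL codes, so
in practice their minimum total is 9. Peak TG, pancreatitis at its
default 0.5, narrower onset bands and abdominal pain remain stochastic.

**What a green test establishes.** The generator provides planted ground
truth with the assumed statistical structure; recovery tests show the
pipeline detects that structure (≥ 90% of planted FCS classified
"likely", ≤ 0.1% of background, every planted case surviving the "7+"
stage). They do not validate the rubric against real patients, real
coding practice, informative missingness, inter-laboratory unit drift or
family structure — none of which the generator models.

## The classification benchmark

Per-patient features are the five aggregates per analyte — highest,
lowest, average, fluctuation and count, with fluctuation defined as the
sample standard deviation (scale-aware and testable; max − min is the
obvious alternative) and undefined below two measurements — plus binary
ICD-10 prefix-group flags. Positives are the planted FCS patients;
negatives a seeded random background sample (class imbalance left as
sampled). Each experiment re-splits both classes 50/50 with a seeded
stratified draw; metrics are AUC (rank/pair-counting definition, ties
one half), plus accuracy/sensitivity/specificity at a fixed 0.5
threshold — fixed deliberately, since under heavy imbalance a
probability-type classifier can show near-zero sensitivity at 0.5 while
its AUC is high, a behavior the benchmark is meant to exhibit rather
than hide.

Four model families are implemented in the package (no suitable
tree/kernel/net packages are available in the target environment, and
owning the tree structure is what makes importance and cut extraction
exact):

* **Gradient boosted trees**: Newton-style split gains
  `G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda)` under
  logistic loss, depth 3, 100 rounds at step 0.3 and minimum child
  hessian 1 (the reference implementation's defaults), sparsity-aware
  splits (each node learns a default direction for missing values) and
  per-tree column subsampling (0.7, seeded), which both decorrelates
  trees and spreads split credit across correlated strong features.
* **AdaBoost**: discrete boosting of depth-2 trees grown by the same
  machinery on weighted ±1 targets.
* **Kernel machine**: regularized least-squares classification
  `(K + lambda I) alpha = y`; linear, cubic-polynomial and RBF kernels
  and ridge penalties {0.01, 0.1, 1} compete on an internal seeded 70/30
  validation split, best refitted on the full training half.
* **ReLU network**: two hidden layers (32, 16), He initialization,
  full-batch Adam at 0.01 for 150 epochs on cross-entropy.

Trees consume raw values so extracted cuts stay in canonical laboratory
units; the kernel machine and the network receive training-median
imputation, missingness indicator columns and train-half z-scoring.

**Importance** sums, over all trees of all supplied ensembles (pooling
gradient-boost and AdaBoost trainings, as the source analysis pooled
"all model trainings"), a weight of `1/(1 + depth)` per split occurrence
— depth-decaying occurrence counting, privileging the early, high splits
that boosting learns first — rescaled so the top feature reads 100.
**Decision cuts** are read from the first trees (default 5) of a boosted
ensemble: each split is reported as (feature, threshold, direction),
the direction positive when the high side of the cut carries the higher
cover-weighted mean leaf value, i.e. pushes toward FCS.

## Numerical choices and degenerate inputs

* Half-up rounding uses a `1e-9` epsilon against binary representation
  of exact halves.
* Empty histories score 0 on every criterion (total 0, not evaluable);
  a lone TG below 2 scores −5.
* AUC requires both classes and errors otherwise; all-tied scores give
  0.5 by the tie convention.
* AdaBoost stops early on a perfect base learner (capped weight) or
  when weighted error reaches 0.5.
* Tree growth stops at depth, at fewer than 2 rows, when no split
  clears the minimum gain, or when a child would fall below the minimum
  hessian mass.
* The column-subsampling, validation-split and net-initialization RNG
  draws run under `.Random.seed`-preserving local seeds, so model
  fitting never perturbs the caller's RNG stream.

## Known limitations

* Fasting-status ascertainment is a stand-in convention; real systems
  record it inconsistently or not at all.
* The onset proxy (first high TG or first pancreatitis) understates
  onset for patients whose symptoms predate their first record.
* Generator parameters are not fitted to any real population; absolute
  prevalence, score distributions and AUCs from synthetic cohorts are
  not comparable to published cohort values, only structural and
  qualitative behavior is.
* The cumulative-vs-disjoint ambiguity of published "k+" distribution
  rows is left open: both conventions are emitted
  (`score_distribution(..., convention =)`) and neither is asserted as
  the source's intent.
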