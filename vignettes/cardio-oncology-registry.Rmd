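---
title: "Methods: EHR phenotyping for a cardio-oncology registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHR phenotyping for a cardio-oncology registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioreg)
```

`cardioreg` implements the computational-phenotyping machinery of an
EHR-based cardio-oncology registry: a cohort of cancer patients treated with
potentially cardiotoxic therapy, followed for left ventricular dysfunction
(LVD), heart failure with reduced ejection fraction (HFrEF), and the care
they receive for it. This vignette records the package's own account of the
methods — the definitions, the timing conventions, the synthetic-data model
and the numerical choices — so that every default can be traced to a reason.

## Cohort definition by value-set expansion

EHR Problem Lists encode diagnoses against a polyhierarchical terminology
(SNOMED CT in practice). A computable cohort definition is a *value set*:
a union of "concept, including descendants" terms minus an analogous union
of exclusion terms. `expand_value_set()` evaluates such rules over a
`concept_hierarchy()`; `problem_list_matches()` applies them, one patient at
a time, with exact string-equality code matching.

Conventions, chosen once:

- A term *includes its anchor concept* as well as its descendants. This is
  the standard "concept, including descendants" semantics; the alternative
  (descendants only) would silently drop patients coded at the anchor.
- The hierarchy is a DAG, not a tree — clinical terminologies are
  polyhierarchical (in the demonstration ontology, *benign neoplasm of
  brain* sits under both *neoplasm of brain* and *benign neoplastic
  disease*). Cycles are rejected at load time by Kahn's algorithm, because a
  cyclic subsumption relation has no coherent descendant semantics.
- Exclusion always wins over inclusion, so the family-history and
  benign-brain-neoplasm brackets remove codes regardless of how many
  include terms cover them.

The test suite checks the engine against an independently written
brute-force oracle — reflexive-free transitive closure by boolean matrix
squaring, followed by plain set arithmetic — on random DAGs of up to 100
nodes.

## Nested cohorts and attrition

`build_cohort()` chains three filters, each conservation-checked through an
`attrition_report()`:

1. **Cancer population**: any Problem-List entry in the cancer value set.
2. **Treated registry**: at least one treatment episode starting inside the
   closed window `[2011-01-01, 2017-06-30]`. The window is closed on both
   ends because "from … until …" in registry descriptions names dates
   meant to be included; both boundary days are tested explicitly.
3. **Baseline-dysfunction exclusion**: any LVEF below 50% *strictly before*
   the initial exposure date, or a systolic-HF / dilated-cardiomyopathy
   Problem-List entry with onset strictly before it.

"Strictly before" resolves a genuine ambiguity: an echocardiogram performed
on the day treatment starts is almost always therapy-baseline imaging, but a
pre/post split keyed on "prior to initiation" has to put the boundary
somewhere. The package resolves the collision once — same-day events are
post-treatment — and applies it consistently in both the exclusion filter
and `summarize_lvef()`, where it is exposed as `same_day_is_post` for
sensitivity analyses. Problem-List entries with no onset date predate
nothing: they cannot justify excluding a patient, and they count as
post-treatment evidence only when no exposure anchor is supplied.

## Phenotype definitions

- **Exposure profile** (`classify_exposure()`): flags for anthracyclines,
  HER2 antibodies, tyrosine kinase inhibitors and immune checkpoint
  inhibitors, set from drug-class membership across *all* episodes; the
  initial exposure date is the earliest episode start.
- **LVD** (`detect_lvd()`): minimum post-treatment LVEF strictly below 50%.
  The *minimum* is used because a single qualifying measure by any modality
  flags the patient; the strictness at exactly 50.0% follows the "LVEF <
  50%" definition and is pinned by tests that perturb values across the
  boundary.
- **HFrEF** (`detect_hfref()`): presence of systolic heart failure and/or
  dilated cardiomyopathy on the Problem List, onset on/after exposure. It
  is deliberately Problem-List-only — no concurrent LVEF requirement — which
  makes it a *documentation-mediated* phenotype: its accuracy against
  clinical truth is exactly what the validation module measures.
- **GDMT** (`classify_gdmt()`): beta-blockers by ingredient match on the
  drug name (carvedilol, metoprolol *succinate*, bisoprolol — tartrate
  formulations never qualify); ACE inhibitors by pharmaceutical class or
  subclass title containing "ACE Inhibitor", or by a named
  combination-product list whose class titles lack the phrase; ARBs by
  angiotensin-receptor-blocker class-title phrases or the standalone token
  `ARB`/`ARBs` (word-bounded, so "Barbiturates" can never match), plus
  aliskiren/valsartan by name; MRAs by subclass title containing
  "Aldosterone Receptor Antagonist". All matching is case-insensitive and
  whitespace-normalized, and adding medications is monotone: an extra row
  can switch flags on, never off. The vocabulary files shipped under
  `inst/extdata/gdmt/` are synthetic stand-ins with realistic cardinalities
  (2 classes + 7 subclasses for ACE inhibitors, 6 ARB classes, 2 MRA
  subclasses, 8 combination products); sites adapt them to their drug
  database.

`phenotype_cohort()` computes all of this table-wise for speed; a dedicated
test cross-checks it row by row against the per-patient functions.

## Validation statistics

Chart-review validation is modelled as stratified sampling
(`sample_for_review()`), dual rating with percent agreement
(`percent_agreement()`), third-reviewer adjudication (`adjudicate()`), and
cross-tabulation into a confusion matrix. `diagnostic_performance()` reports
sensitivity, specificity, PPV and NPV, each with an exact (Clopper–Pearson)
two-sided interval computed by inverting the binomial tails (beta-quantile
form, cross-checked in tests against `binom.test()`):

```{r}
diagnostic_performance(confusion_matrix(tp = 40, fp = 10, fn = 0, tn = 50))
```

Choices worth recording:

- **Exact intervals everywhere.** For a 40/40 sensitivity the exact lower
  bound is 0.912 — the one number an asymptotic interval cannot produce.
  Published PPV/NPV intervals in this literature sometimes follow other
  (often unstated) constructions; the package computes Clopper–Pearson
  uniformly rather than reverse-engineering an unknown method, and tests
  only assert interval properties the exact method guarantees (coverage at
  least nominal; width decreasing in trials).
- **Degenerate denominators are flags, not sentinels.** A metric whose
  denominator is zero is reported with `defined = FALSE` and `NA` values —
  never an "N/A" string or a silent 100%.
- **Back-solving counts** (`confusion_from_predictive_values()`) requires
  `ppv * n` and `npv * n` to be integral to within 1e-6, so rounded
  published values can never silently invent review counts.
- Display rounding is half-up at one decimal
  (`round_half_up()`), the convention of clinical tables; base R's
  round-half-to-even would turn 95.25 into 95.2.

## The synthetic cohort generator

There is no public patient-level data for a registry like this, so
`generate_cohort()` simulates one with known per-patient truth. Its defaults
*are* the study conditions the package targets, fixed once from the
published registry structure:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 8275 | treated registry size |
| `exposure_probs` | AC .1778, HER2 .0495, TKI .0882, ICI .0031 | mutually exclusive exposure classes |
| `pre_screen_prob` | AC .2588, HER2 .278, other .1785 | P(pre-treatment LVEF assessment); the "other" value is back-solved so the overall rate is 19.77% |
| `post_screen_prob` | AC .691, HER2 .851, other .32 | P(post-treatment assessment) |
| `lvd_risk` | AC .042, HER2 .049, other .126 | P(true LVD \| post-assessed) |
| `hfref_prev` | AC .0357, HER2 .0902, other .0198 | P(true HFrEF), ≈2.5% overall |
| `hfref_doc_sensitivity/specificity` | .953 / .835 | Problem-List documentation channel |
| `baseline_dysfunction_prob` | 372/8275 | pre-treatment LVD/HF rate |
| `referral_prob_given_outcome` | .639 | cardiology referral among outcome patients |
| `gdmt_probs` | BB .441/.188, ACEi-ARB .474/.306, MRA .118/.024 | referred / not referred |

Mechanisms:

- **LVEF values** are truncated normal: mean 40, SD 6 on \[5, 49.5\] for
  true-LVD patients; mean 60, SD 5 on \[50, 80\] otherwise. No distribution
  is published for these values; the two regimes straddle the 50% threshold
  realistically while keeping the generated truth exactly recoverable,
  which is what makes the pipeline's deterministic stages testable. A
  measurement-noise overlap can be created by widening the truncation
  bounds.
- **HFrEF documentation** is a per-patient Bernoulli channel conditioned on
  true status — the simplest mechanism that reproduces an imperfect
  sensitivity/specificity pair. A consequence worth knowing: with ≈2.5%
  true prevalence and 83.5% specificity, most *documented* HFrEF entries in
  the synthetic data are channel false positives, so the documented rate
  (≈18%) far exceeds true prevalence. That is the configured channel
  operating on a low-prevalence truth, and it is precisely the situation
  that makes PPV validation interesting.
- **Ages** are truncated normal (median 63, SD 14, bounds 18–95);
  demographics, comorbidities, vital status and sex are independent
  Bernoulli draws at their configured fractions.
- **One treatment episode per patient**, start date uniform over the
  window — the single-start-date simplification registries of this kind
  themselves use; episode-level analyses are out of scope.
- **GDMT assignment** draws each drug class independently per outcome
  patient at the referral-stratified probability, then realizes it as a
  concrete medication row that exercises a *different* matching rule each
  time (plain class titles, phrase-bearing subclasses, combination
  products, aliskiren/valsartan). Distractor medications — statins,
  metformin, metoprolol tartrate, a barbiturate — are added to 40% of
  patients and are deliberate near-misses for the matchers. ACE inhibitors
  prescribed for hypertension are simulated only in non-outcome patients,
  so that the configured GDMT probabilities remain the exact truth for the
  outcome stratum the care-gap report measures.

Determinism: the dataset is a pure function of `(config, seed)`, and
generation saves and restores the caller's RNG state.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: Problem-List incompleteness and coding drift
(cancer diagnoses are always coded), inter-facility care fragmentation
(no outside-hospital imaging), correlated comorbidity structure, multiple
or recurrent treatment episodes, LVEF measurement error across modalities,
and any dependence of documentation quality on clinical severity. Results
on synthetic data certify the *pipeline logic*, not institutional data
quality.

## Problem sizes in the test suite

Statistical tests run at sizes where a 3-standard-error binomial check is
meaningful but cheap: marginal-rate recovery at n = 5000; the
documentation-channel study at 100 seeds × 5000 patients with true HFrEF
prevalence enriched to 0.30 (so the sensitivity denominator is ≈1500 and
its exact CI is a few points wide), asserting that the configured 0.953 /
0.835 fall inside their intervals in at least 90 of 100 seeds;
Clopper–Pearson coverage by Monte Carlo at 10,000 replicates per (p, n)
cell. The oracle-equivalence suite uses random DAGs of 20–100 nodes, the
scale at which closure-by-matrix-squaring is instant.

## Known limitations

- Chi-squared comparisons default to *no* continuity correction
  (`chisq_2x2()`), matching the squared two-proportion z-test; with Yates
  correction the same data give systematically larger p-values, so the flag
  is explicit rather than hidden.
- The care-gap report treats the active medication list at a single
  as-of date; dose, duration, adherence and contraindications are out of
  scope.
- HFrEF is Problem-List-only by definition; its divergence from clinical
  truth is a measurement property to be validated, not a bug, and the
  validation module exists to quantify it.
- Quartiles use inclusive linear interpolation (`stats::quantile` type 7);
  other quartile conventions can shift IQR endpoints by a unit on small
  samples.
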