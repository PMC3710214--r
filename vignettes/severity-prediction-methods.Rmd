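---
title: "Methods: three-step severity prediction in MPS I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-step severity prediction in MPS I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsipredict)
```

## The decision problem

Newborn screening can diagnose mucopolysaccharidosis type I before any
phenotype is clinically apparent, but the treatment decision — early
haematopoietic stem cell transplantation for the severe Hurler phenotype
(H) versus enzyme replacement for the attenuated Hurler–Scheie and Scheie
phenotypes (non-H) — cannot wait for the clinical course. `mpsipredict`
implements a categorical three-step classifier over data obtainable in the
first month of life. Each step either decides or defers:

1. genotype: both alleles on a severe-mutation list ⇒ **H**;
2. residual fibroblast IDUA activity: at or below the rule-in cut-off ⇒
   **H**; above the rule-out cut-off ⇒ **non-H**; the gray zone defers, as
   does a missing measurement;
3. clinical findings: upper respiratory tract obstruction or inguinal
   hernia present ⇒ **H**; both known-absent ⇒ **non-H**; otherwise
   **indeterminate**.

The model is deliberately rule-based and produces no probabilities: at the
reference cohort's size (n = 30) a calibrated probabilistic output would
be illusory precision, and the clinical question is categorical.

### Assumptions

* The H vs non-H dichotomy (HS and S pooled as non-H) tracks the treatment
  indication; no sub-stratification of HS by neurocognitive risk is
  attempted.
* The severe-mutation list is one-sided evidence. Its alleles reliably
  predict H in homozygous or compound-heterozygous combination, but
  absence from the list means nothing: attenuated-associated alleles vary
  in effect with allelic context and modifier genes, so the genotype step
  never emits non-H.
* Fibroblast activity is assayed under the optimized protocol the cut-offs
  were derived for (1 mM substrate, 2 h incubation, 0.5 mg·ml⁻¹ protein,
  one week postconfluency). Thresholds are not transferable across assay
  protocols without re-derivation; the documented inter-assay CV of ~18%
  is the reason the package exposes `derive_thresholds()` rather than
  hard-wiring the constants everywhere.
* Clinical signs are informative only in term births; prematurity itself
  causes respiratory signs and hernias.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `severe_list` | 25 alleles | — | curated Hurler-associated mutations; swappable because allele spectra differ between populations |
| `thresholds$lower` | 0.32 | nmol·mg⁻¹·hr⁻¹ | highest observed cut-off with 100% rule-in specificity on the reference data |
| `thresholds$upper` | 0.66 | nmol·mg⁻¹·hr⁻¹ | cut-off achieving 100% rule-out sensitivity (no H line above it) |
| `preterm_policy` | `"skip-clinical"` | — | preterm signs treated as confounded; `"use-clinical"` available for sensitivity analysis |
| `min_n` (screen) | 10 | patients | below this an exact test on a 2×2 of newborn-chart data is uninformative; sparse features report "not computed" |

## Numerical and convention choices

**Inclusive lower boundary.** The H-zone is `activity <= lower`, although
the rule is often quoted as "below 0.32". One reference Hurler line has
activity exactly 0.32, and the printed rule-in sensitivity of 56% (5/9)
— as well as the complete algorithm's 100% sensitivity — requires that
value to fall in the H-zone. The upper boundary is exclusive upward
(`> upper` ⇒ non-H), making the gray zone the half-open interval
`(lower, upper]`; no observed value sits exactly at 0.66, so that choice
is free and we keep the zone map total.

**Boundaries at observed values.** `derive_thresholds()` reports the
rule-in boundary as the largest observed activity below every non-H
sample, and the rule-out boundary as the largest observed H activity —
not interpolated midpoints. On the reference activities this yields
0.32 / 0.58; the packaged default upper cut-off is nevertheless pinned at
the published 0.66, which no midpoint convention reproduces from the 18
observed points (the smallest non-H value above all H lines is 0.77). All
zone-membership performance numbers are identical under either upper
boundary, because no observed value lies in (0.58, 0.77].

**Ties and degenerate inputs.** A cross-class tie at a candidate rule-in
boundary breaks toward the smaller H-zone, preserving 100% rule-in
specificity by construction. If the smallest observed value is non-H, no
valid rule-in boundary exists: the report carries `separable = FALSE` and
an H-zone of width 0, rather than a silent fallback. Perfectly separated
classes collapse the gray zone to width 0 at the largest H value.

**Exact tests.** The two-sided Fisher test uses the probability-based
definition — the sum of hypergeometric probabilities (computed via
log-binomial coefficients) of every table with the observed margins no
more probable than the observed table, with a relative tolerance of 1e-7
on the comparison — matching standard statistical packages. The exact
Mann–Whitney p-value enumerates the full null distribution of U by
dynamic programming over rank subsets when the smaller group has at most
12 observations and there are no ties (where the U distribution is
symmetric, so the |U − n₁n₂/2| definition coincides with the usual
doubled tail); with ties or larger groups it falls back to seeded
Monte-Carlo permutation with at least 10⁵ draws. AUC is oriented "low
value = positive" throughout, matching the direction in which residual
activity discriminates.

**Rounding.** Published percentages are integer, rounded half-up
(82.35 → 82, 55.6 → 56, 88.9 → 89); AUC is reported to three decimals.
Raw fractions are always retained in the report objects; rounding happens
only at presentation.

## Missing-data policy

Missing values are never imputed into a verdict:

* a missing activity measurement skips from the genotype step directly to
  the clinical step — four reference patients lack fibroblast lines yet
  are correctly classified, which fixes this policy;
* one absent and one unknown clinical finding defers rather than calling
  non-H (absence of evidence on one feature is not evidence of absence);
* unknown gestational age is treated as term — the overwhelming
  population prior — with the parse flagging the record; in the reference
  cohort all three such patients are resolved before the clinical step,
  so the choice cannot alter its results;
* a patient undecided after all steps is `indeterminate`. Evaluation
  excludes indeterminates from the sensitivity/specificity denominators
  and reports their count: this is the only reading under which a cohort
  containing a patient with no usable step-2/step-3 data can show 100%
  sensitivity and specificity, and the report makes the exclusion
  explicit rather than hiding it.

One asymmetry deserves note. The genotype step *alone* is evaluated as a
binary screen: an unflagged patient counts as a negative call, giving
sensitivity 14/17 (82%) and specificity 13/13 (100%) on the reference
cohort. Inside the composed algorithm the same non-flag is a deferral,
not a negative call. Both views are correct for their purpose — the
screen view measures the step, the deferral view composes it.

## The synthetic-cohort generator

`simulate_cohort()` draws cohorts with the statistical structure the
algorithm assumes: phenotype labels from a configurable mix; genotypes
such that H patients carry two severe-pool alleles with probability
`p_both_severe_given_H` while non-H patients never do; per-phenotype
log-normal activities; phenotype-conditional Bernoulli clinical findings;
and independent per-field missingness. Defaults are moment-matched to the
packaged cohort: mix 17:6:7, `p_both_severe_given_H = 14/17`, H activity
mass ≈ 0.23–0.58 and S mass ≈ 1.05–1.70 nmol·mg⁻¹·hr⁻¹ with HS straddling
the gray zone, finding prevalences at the observed term-cohort fractions,
missingness at the observed per-field rates, and a 10% preterm rate.
The log-normal choice reflects only that activities are positive and span
an order of magnitude; it is an emulation target, not a biological claim.

What the generator does **not** emulate: assay noise structure (the
inter-assay CV), correlation between findings beyond their shared
phenotype dependence, informative missingness (fields are masked
independently at random, whereas real chart availability correlates with
illness severity), population allele frequencies, and any association
between genotype class and activity level within a phenotype. Passing
property tests on synthetic cohorts therefore demonstrates internal
consistency of derivation, prediction and evaluation — not external
validity on real screening data.

## Problem sizes used in the tests

The packaged analyses are desk-scale (30 patients, 18 activities) and
deterministic. Property tests use seeded replicates sized for precision
without waste: 20 replicates for threshold recovery on separated
synthetic cohorts of n = 30; 1,000 label permutations for the screen's
type-I sanity check; exhaustive enumeration oracles for group sizes up to
10; and a single n = 10⁴ cohort for prevalence convergence (±3 binomial
standard deviations).

## Known limitations

* The algorithm is internally validated on the cohort that built it;
  performance estimates are optimistic and the package makes no
  cross-validation claim (none is possible at n = 30 without breaking the
  published construction).
* The severe-mutation list is a static snapshot; regional allele spectra
  and newly observed mutations shift the genotype step's sensitivity, and
  the list is therefore an explicit, swappable input.
* The per-patient fixture carries only the two clinical findings the
  screen selected; the remaining screened characteristics exist in the
  source only as availability counts, so the screen's behavior on sparse
  features is exercised on synthetic data.
* Activity thresholds are assay-protocol-specific (see above).
* Early thoraco-lumbar kyphosis, a promising discriminator, is absent
  because it is rarely recognized in retrospective newborn charts.
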