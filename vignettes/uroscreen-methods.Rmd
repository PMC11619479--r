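---
title: "Methods: urine flow-cytometry UTI screening and the scattergram-angle rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urine flow-cytometry UTI screening and the scattergram-angle rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroscreen)
```

## The problem

Urine culture is the gold standard for diagnosing urinary tract infection,
but the large majority of specimens sent to a clinical microbiology
laboratory grow nothing. Automated urine flow cytometry (the Sysmex
UF-5000 family) counts bacteria (BACT), leukocytes (WBC), yeast-like cells
and epithelial cells per µL within minutes, and reports research channel
intensities for the bacterial cluster: forward scatter (B_FSC, a particle
size proxy) and fluorescence (B_FLH, a nucleic-acid staining proxy). Two
clinical questions follow:

1. **Screening**: what BACT cut-off excludes culture-negative urines with
   an acceptable false-negative rate, and how much culture workload does
   that save?
2. **Gram prediction**: can the bacterial scattergram anticipate the Gram
   class of the organism — and hence early empiric therapy — before
   culture results exist?

`uroscreen` implements both analyses plus the agreement analysis between
the instrument's categorical bacterial-information flags and culture.

## Screening model

Culture positivity is binary at a stated colony-count criterion
(≥10^4^ or ≥10^5^ CFU/mL; growth of more than two species is a
contaminated culture and yeast growth is not a bacterial positive — both
are excluded upstream by `join_cohort()`). For a marker $x$ the positive
call is $x \ge c$. The empirical ROC curve enumerates every distinct
observed value of $x$ (plus $\pm\infty$ sentinels); the trapezoidal AUC
then equals the Mann–Whitney concordance probability
$P(x_{pos} > x_{neg}) + \tfrac12 P(x_{pos} = x_{neg})$, which the test
suite verifies against brute-force pair counting. The 95% CI uses
DeLong's variance (the default of common clinical ROC software), with a
seeded 2,000-resample bootstrap available.

**Cut-off at a sensitivity target.** Screening tables are indexed by
nominal sensitivity (80, 85, 90, 95, 97.5, 99%). Published tables rarely
state the selection rule, so the package fixes one and names it: among all
observed cut-offs, return the **largest** whose achieved sensitivity still
meets the target. Since specificity is non-decreasing in the cut-off, this
maximizes specificity subject to the sensitivity floor; the smallest
observed score always achieves 100% sensitivity, so a solution exists for
every attainable target. An exhaustive-search oracle confirms the
selection exactly.

**Workload.** With only screen-positives cultured, culture reduction is
$(TN+FN)/N$ and the false-negative rate among avoided cultures is
$FN/(TN+FN)$. Metrics are kept unrounded internally (the Bayes identity
$PPV = \frac{SEN\,\pi}{SEN\,\pi + (1-SPE)(1-\pi)}$ holds exactly on the
stored values); reports round half-up to one decimal, the convention of
clinical tables. A metric with a zero denominator is reported as
undefined, never as 0.

**Combined marker.** Where BACT and WBC are combined, a two-covariate
linear logistic score on $\log(x+1)$ counts is used. Published screening
evaluations generally do not state their combination rule; this choice is
the standard risk-score construction, and results from it are treated as
exploratory.

**Median comparisons** between groups use the two-sided Mann–Whitney U
test: the quantities compared are medians of strongly right-skewed
instrument counts, for which a rank test is the conventional choice.

## Flag agreement

Flags (Gram Pos?, Gram Neg?, Gram Pos/Neg?, Unclassified, UTI, No flag)
are cross-tabulated against culture categories (Gram-positive,
Gram-negative, mixed, negative) for specimens at or above a BACT cut-off
(default 42.2/µL, a 95%-sensitivity screening cut-off). Two-species
cultures of one Gram class count as that class; only cross-Gram pairs form
the mixed column. Cohen's kappa needs a square table, and the collapsing
that produces one is consequential — published kappas for this instrument
range roughly 0.2–0.4 on similar data, and no collapsing of the bundled
reference table reproduces every historically reported value. The package
therefore treats the scheme as a named, reported parameter:

- `three_class` (default): {GP, GN, Other};
- `four_class`: {GP, GN, Mixed, Negative} (Gram Pos/Neg → Mixed;
  Unclassified, UTI and No flag → Negative).

On the bundled reference table these give κ = 0.371 and 0.379. Kappa is
unweighted (the categories are nominal) and reported with P₀ and Pₑ;
Pₑ = 1 yields an explicitly undefined kappa.

The per-flag binary view (`gram_flag_metrics()`) scores one Gram flag
against all others and that Gram culture column against all others, the
mixed column counting as non-target: on the reference table the
Gram-negative flag has PPV 109/125 = 87.2% and specificity 252/268 =
94.0%, while the Gram-positive flag reaches only 26/96 = 27.1% — the
thick peptidoglycan wall of Gram-positives resists the fluorescent dye,
and the instrument's eligibility rule (below) leaves bacteriuria without
pyuria unflagged.

## The scattergram-angle rule

With B_FLH on the abscissa and B_FSC on the ordinate, a specimen's
bacterial cluster lies along a ray of slope $r = \mathrm{B\_FSC}/
\mathrm{B\_FLH}$ at angle $\theta = \arctan r$ from the X-axis. The
geometry is fixed by the observation that the published threshold angle
28° matches $\arctan(0.55) = 28.81°$ truncated toward zero — so integer
angle reporting truncates, while the full-precision angle is retained for
classification.

`fit_ratio_cutoff()` chooses the ratio cut-off maximizing the Youden index
$J = SEN + SPE - 1$ over midpoints between adjacent distinct observed
ratios, Gram-negative being the positive class called at ratio ≤ cut-off;
ties break toward higher sensitivity. Youden's index is the standard
"optimal ROC cut-off" criterion when the selection rule is otherwise
unstated. `classify_by_angle()` applies the strict rule *angle < threshold
⇒ Gram-negative* (a boundary angle is the non-Gram-negative call: the
published validation table has `<28°` and `>28°` bands and no equality
band, so ties go conservatively to the non-GN side) to culture-positive
specimens with BACT ≥ 42.2/µL, skipping and counting records with missing
channel values.

## The synthetic-cohort generator

No per-patient dataset is distributed with published evaluations of this
instrument, so the package ships a generator whose defaults *are* the
study conditions, fixed once in `make_default_config()`:

- 31/823 of specimens yeast-positive; 31.8% of non-yeast specimens
  culture-positive at ≥10^4^ CFU/mL; 88.5% of positives at ≥10^5^;
  78% of bacterial positives Gram-negative (reference-table margins give
  ≈0.79 and the validation cohort 80.7%); two-species cultures at 8/252
  with one quarter cross-Gram; contaminated cultures off by default;
  training arm fraction 823/1522.
- **BACT** per µL is log-normal per stratum. The spreads are not free
  guesses: they are solved analytically from the published screening
  table's own quantiles (positives: cut-offs 42.2 and 440.8/µL at 95% and
  80% sensitivity ⇒ meanlog 8.55, sdlog 2.92; negatives: specificities
  60.1% and 89.6% at the same cut-offs ⇒ meanlog 3.14, sdlog 2.34). The
  implied asymptotic AUC, $\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_0^2+
  \sigma_1^2}\big) = 0.926$, lands inside the published 0.927 without
  being tuned to it.
- **WBC** log-normal with medians 12 (negatives) and 45/µL (positives),
  sdlog 1.6/1.8 — clinically plausible pyuria levels whose implied AUC is
  0.708, matching the much weaker discrimination reported for WBC.
- **(B_FSC, B_FLH)** bivariate log-normal per Gram class with medians
  (31.6, 101.2) ch for GN and (59.8, 87.6) ch for GP and log-scale
  correlation 0 (no published dispersion or correlation exists; these are
  calibration choices, not reported facts). The quadrature ratio spreads
  (0.344 GN, 0.144 GP) are solved from the published operating point of
  the ratio rule — 95.0% sensitivity and 93.3% specificity at cut-off
  0.55 — and the split of each spread between the two channels is a free
  choice (GN 0.20/0.28, GP 0.11/0.093). Culture-negative and yeast
  specimens draw from a diffuse low-signal background law.
- **Flags**: eligibility is exactly WBC ≥ 10/µL AND BACT ≥ 100/µL
  (ineligible ⇒ No flag); eligible specimens draw a flag from a per-class
  categorical distribution fitted once so the simulated cross-tab is
  qualitatively like the reference table (GN column dominated by the GN
  flag; negatives spread over UTI/Unclassified/Gram Pos). Exact reference
  frequencies are not a generator contract. `flag_noise_exact()` gives the
  noise-free point masses used in tests.

Everything is seeded: identical configurations produce byte-identical
cohorts, with the flag stage on a derived sub-seed.

**What the generator does not emulate.** Instrument optics and carryover,
antibiotic-pretreatment effects on bacterial shape, mucus/turbidity/
haematuria interference, within-sample correlation between counts and
channels beyond class membership, and day-to-day drift. One consequence is
visible: because the channel spreads are constrained by the ratio rule's
operating point, the simulated GN-vs-GP contrast in B_FLH is more
significant than the borderline contrast seen on real specimens. Passing
tests therefore demonstrate the correctness and calibration of the
*analysis machinery* under the stated statistical structure, not the
field performance of the instrument.

## Numerical conventions and problem sizes

- Positivity is always *score ≥ cut-off*; ROC sentinels at ±∞.
- Percentages round half-up to one decimal in reports only; AUC to three
  decimals; all internal arithmetic is unrounded.
- Degenerate inputs: single-class labels error; zero denominators give
  `NA` metrics; an all-tie score vector gives AUC 0.5; the Youden fit
  flags J = 0 as low separability.
- Test and acceptance simulations use n = 10,000 cohorts for calibration
  checks (prevalence within ±0.02, channel medians within ±0.5 ch, BACT
  AUC within [0.90, 0.95]) and 100 replicates of 80 GN / 15 GP specimens
  for the ratio-cut-off recovery check (within ±0.10 of 0.55 in ≥90% of
  replicates) — sizes chosen to make Monte-Carlo error small relative to
  each tolerance while keeping the default suite fast.

## Known limitations

- The kappa reported for any real dataset depends on the collapsing
  scheme; comparisons across publications that do not state their scheme
  are not meaningful, which is why the scheme is part of the result object.
- The cut-off-at-sensitivity rule reproduces published tables' counts but
  not always their last printed decimal of SPE/PPV (one reference column
  disagrees with its own counts by 0.1; the counts are treated as
  authoritative).
- How training specimens "without background interference" were screened
  for ratio-rule fitting is not recoverable; the generator has no
  background-interference exclusion rule, and the fitted-cut-off check
  simply subsamples 80 GN / 15 GP specimens.
- `combine_markers()` is a modelling choice, not a reproduction of any
  published combination rule.
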