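---
title: "Validating behavioral pain scales around nursing procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating behavioral pain scales around nursing procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painscales)
```

## The problem

Mechanically ventilated ICU patients frequently cannot self-report pain.
Two observational instruments are in wide clinical use: the **Behavioral
Pain Scale** (BPS: facial expression, upper-limb movement, ventilator
compliance; each item 1–4, total 3–12) and the **Critical-Care Pain
Observation Tool** (CPOT: facial expression, body movements, muscle
tension, ventilator compliance; each item 0–2, total 0–8). In conscious
patients the self-reported **visual analog scale** (VAS, 0–10) is the
gold standard, with VAS ≥ 3 conventionally defining "pain present".

`painscales` scores both instruments, fuses them into a **combined
score** — the arithmetic sum of the two totals, spanning 3–20 — and runs
the validity battery used to evaluate such scales around a standardized
nursing procedure observed at three phases: 1 min *before*, *during*,
and 20 min *after* the procedure. Both totals map onto a shared
three-level severity grading: BPS 3–4 / CPOT 0–2 *absence*, BPS 5–7 /
CPOT 3–4 *moderate*, BPS 8–12 / CPOT 5–8 *severe*. The combined score is
deliberately the plain sum: no weighting or rescaling, because only the
plain sum preserves the published 3–20 range and keeps the fused score
interpretable at the bedside.

## The validity battery

`run_analysis()` computes five sections from a long-format observation
table (one row per patient × session-day × phase):

* **Discriminant validity.** If a scale measures pain, its score must
  rise during a painful procedure. Scale totals are compared across
  phase pairs (before–during, during–after, before–after) with a paired
  Wilcoxon signed-rank test, pairing rows by patient and session-day,
  overall and within each consciousness stratum. Zero differences are
  dropped before ranking, ties get average ranks, and the positive-rank
  sum is standardized with the tie-corrected variance
  $n(n+1)(2n+1)/24 - \sum_t (t^3-t)/48$. A continuity correction of one
  half toward the mean is applied: on tie-free instances with 10–15
  informative pairs the corrected two-sided normal p stays within 0.02
  of the exact sign-flip enumeration, while the uncorrected version
  deviates by up to 0.05 — we checked both by enumeration, and adopted
  the correction (also the default in `stats::wilcox.test` and common
  clinical software). The Z sign follows *first phase − second phase*,
  so pain rising during nursing yields a negative before-vs-during Z.

* **Criterion validity.** Spearman rank correlation ($r_s$, Pearson on
  average ranks; two-sided p from the t approximation on $n-2$ degrees
  of freedom) of each scale total against VAS, on all rows carrying a
  VAS.

* **Diagnostic performance.** Empirical ROC curves of each scale
  against the dichotomized VAS (≥ 3), with positivity rule
  *score ≥ cutoff*, one operating point per distinct observed score plus
  a sentinel above the maximum. The AUC is the trapezoidal area, which
  equals the Mann–Whitney probability with ties counted one half. No
  published positivity cutoff exists for these scales (or for the
  combined 3–20 score), so the package reports the **Youden-optimal**
  point ($\max$ sensitivity + specificity − 1, ties broken toward the
  lower, more sensitive cutoff) alongside the full curve. Accuracy is
  **prevalence-weighted**: sensitivity × prevalence of positives +
  specificity × prevalence of negatives, i.e. the probability of a
  correct call at the study's class balance. Per-phase tables and an
  *overall* column pooling all phases into a single ROC are produced.

* **Agreement.** Quadratic-weighted Cohen's kappa between the BPS and
  CPOT severity categories, per phase and overall. Kappa needs a common
  category set, and the absence/moderate/severe bands are the only
  categorical alignment shared by the two instruments. Weights are
  $w_{ij} = 1 - ((i-j)/(k-1))^2$; expected agreement comes from the
  product of marginals. Values above 0.6 are conventionally read as
  good agreement.

* **Item importance.** Unpaired Cohen's d (pooled SD with $n-1$
  denominators) of each of the seven items between the before and
  during phases, labeled with the standard magnitude bands: |d| < 0.2
  negligible, 0.2–0.5 small, 0.5–0.8 medium, 0.8–1.3 large, > 1.3 very
  large. The unpaired formulation matches the bands' calibration; the
  paired structure is already exploited by the Wilcoxon stage.

Stages that hit degenerate inputs (a missing phase, single-class
labels, constant scores) are skipped with a warning instead of aborting
the run, so partial designs still produce the computable sections.

```{r battery}
obs <- simulate_cohort(cohort_config(seed = 4))
report <- run_analysis(obs)
report
report$agreement
```

## The synthetic cohort

No public dataset carries this design, so `simulate_cohort()` generates
one. Its defaults *are* the emulated study conditions: 101 patients (41
conscious, 60 unconscious), 3 session-days each, 3 phases per session —
303 observation sessions, 909 rows; VAS only on conscious rows.

The generative model is deliberately the simplest structure consistent
with "more pain → higher items":

1. **Latent pain** is anchored to VAS units. For patient $p$, session
   $s$, phase $f$:
   $\theta = \mu_f + b_p + e_{psf}$, clipped to $[0, 10]$, with
   $b_p \sim N(0, \sigma^2)$ a patient random effect and
   $e_{psf} \sim N(0, \sigma^2)$ session noise ($\sigma$ =
   `latent_sd` = 1.2). Default phase means are 1.5 (before), 4.5
   (during), 2.0 (after): the procedure lifts typical pain into the
   moderate band and it relaxes back afterwards, matching the
   rise-and-return pattern such studies report.
2. **Ordinal readout.** Each behavioral domain $d$ has a discrimination
   slope $\lambda_d$; the scaled signal $\lambda_d(\theta - a)$ (anchor
   $a$ = 2.5, just below the VAS pain threshold) is cut at two
   thresholds (1, 3) into three behavior levels — a cumulative-threshold
   (proportional-odds-like) mechanism.
3. **Crosswalk.** Levels map to concordant BPS/CPOT item pairs via
   `behavior_to_items()`. Where a correspondence row spans two BPS
   values ("3 or 4"), a sub-intensity flag (Bernoulli 0.5) picks one,
   keeping the deterministic mapping separate from the randomness. At
   the middle movement level the CPOT body-movement and muscle-tension
   items are fixed at 1/1 — the row's nominal labels — which keeps the
   per-domain sum inside the printed band; the printed "0 or 1"
   alternatives surface only through discordance noise.
4. **Discordance noise** perturbs each item by ±1 level independently
   with probability 0.05 (clipped to the item range), so the two
   instruments agree well but not perfectly, as real raters do.
5. **VAS readout** for conscious patients is
   `round(clip(theta + N(0, vas_noise_sd), 0, 10))` with
   `vas_noise_sd` = 2.5.

Unconscious patients share the identical latent and behavioral model
and differ only in VAS missingness, mirroring the clinical claim that
nursing care is painful independent of sedation level. All draws come
from one seeded stream in fixed order (patients → sessions → phases →
domains), so a config fully determines every output byte.

### Calibration

The discrimination slopes (facial 1.10, movement 0.35, ventilator 0.45)
were chosen once, by a grid search of the package's *analytic*
expected-effect function (`expected_item_effects()`, normal integrals —
no simulation) against the per-item effect-size pattern reported for
this design: facial expression dominant near 1.4, upper-limb movement
near 0.84, ventilator compliance near 1.0, CPOT movement items smaller.
With `vas_noise_sd` = 2.5 the criterion correlations land in the
published 0.48–0.56 range. Because the generator gives both movement
items one shared level, their expected effects coincide (≈ 0.78) where
real data showed 0.60 and 0.71 — a known simplification.

```{r calibration}
expected_item_effects(cohort_config())
```

`expected_item_effects()` doubles as the parameter-recovery oracle: the
tests require the simulated facial effect (via `cohens_d`) to match the
analytic value within ±0.25 at the default size, and to rank first
among the seven items in the large majority of seeded runs.

### What the generator does and does not emulate

It reproduces the design counts, the phase trajectory, the facial-item
dominance, criterion correlations and severity-level agreement of the
emulated study. It does **not** model sedation depth or drug dosing,
delirium, day-to-day carryover beyond the patient random effect,
rater-specific bias, or early extubation (every synthetic patient
completes all 3 sessions, whereas real patients could drop out after
extubation). Tests passing on synthetic cohorts therefore validate the
*pipeline machinery and its statistics*, not any clinical claim about
real patients.

## Numerical conventions and edge cases

* Scores are validated as integers in their ranges; non-integers and
  out-of-range values are rejected with the item (and, for CSV input,
  the row) named. Severity bands are closed integer bands — no
  interpolation.
* Reported percentages are rounded **half-up** to 2 decimals
  (`74.675 → 74.68`), the convention of printed clinical tables, rather
  than R's default half-even.
* Wilcoxon: zeros dropped, average ranks, tie-corrected variance,
  continuity correction; all-zero differences raise a degenerate-input
  error. Two-sided p-values throughout the package.
* Spearman: |rs| = 1 returns p = 0 (the t statistic diverges).
* ROC: cutoffs scan the observed distinct values plus one sentinel;
  all-tied scores give AUC 0.5. Youden ties break toward the lower
  cutoff.
* Kappa: expected agreement of 1 (both raters constant) raises a
  degenerate-input error rather than 0/0.
* `run_analysis()` skips degenerate stages with a warning; the combined
  score's pooled AUC is asserted (in tests) not to fall more than 0.05
  below the better single scale — strict superiority of the fusion is
  *not* asserted, since on this battery the combined AUC is typically
  close to the better component rather than above it.

## Problem sizes in the test suite

The bundled tests run the full battery on default-size cohorts (909
rows) across 10 seeds for recovery checks, enumerate all 5 184 item
combinations for the score ranges, check the trapezoidal AUC against
brute-force pair enumeration on 200 random instances (n ≤ 30), and the
Wilcoxon approximation against exact sign-flip enumeration at n =
10–15. These sizes make the whole suite run in about two minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Limitations

The package validates instruments against the dichotomized VAS in
conscious patients only — exactly the limitation of the underlying
design: in unconscious patients there is no gold standard, so only
discriminant validity and inter-scale agreement are available there. No
confidence intervals are reported for AUC or kappa, and no
multiple-testing correction is applied across the battery's many tests;
users comparing many scales or items should adjust accordingly.
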