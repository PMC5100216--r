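# painscales

Scoring and validity analysis of behavioral pain scales for critically
ill, mechanically ventilated patients.

Patients under mechanical ventilation often cannot self-report pain, so
ICU teams rely on observational instruments: the **Behavioral Pain
Scale** (BPS — facial expression, upper-limb movement, ventilator
compliance; items 1–4, total 3–12) and the **Critical-Care Pain
Observation Tool** (CPOT — facial expression, body movements, muscle
tension, ventilator compliance; items 0–2, total 0–8). `painscales` is
for clinical researchers evaluating such instruments around a painful
procedure observed at three phases (before / during / after nursing
care). It provides:

- instrument scoring, the fused **combination score**
  `combined = BPS + CPOT` (range 3–20), and the shared severity bands
  (BPS 3–4 / CPOT 0–2 *absence*; BPS 5–7 / CPOT 3–4 *moderate*;
  BPS 8–12 / CPOT 5–8 *severe*);
- the full validity battery: **discriminant validity** (paired Wilcoxon
  signed-rank Z across phases), **criterion validity** (Spearman r_s
  against the visual analog scale, VAS 0–10, gold standard in conscious
  patients), **diagnostic performance** (empirical ROC against the
  VAS ≥ 3 pain label, Youden-optimal cutoff, trapezoidal AUC, and
  prevalence-weighted accuracy
  `sens · n_pos/n + spec · n_neg/n`), **agreement**
  (quadratic-weighted kappa between the two instruments' severity
  categories), and **item importance** (before-vs-during Cohen's d per
  item with the standard magnitude bands);
- a seeded **synthetic-cohort generator** emulating the study design —
  101 patients (41 conscious / 60 unconscious) × 3 session-days × 3
  phases — so the entire pipeline is testable without clinical data;
- CSV in/out, deterministic report files, and a small CLI
  (`inst/cli/painscales.R`, verbs `simulate` / `analyze` / `demo`).

## Worked example

```r
library(painscales)

obs <- simulate_cohort(cohort_config(seed = 4))   # 909 rows, 101 patients
report <- run_analysis(obs)
report
#> Pain-scale validity report: 909 rows, 101 patients, 369 with VAS
#>   discriminant: 27 tests | criterion: 3 scales | performance: 12 cells | agreement: 4 phases | items: 7

write_report(report, "report")
cat(readLines("report/summary.txt"), sep = "\n")
#> Pain-scale validity report
#> rows: 909  patients: 101  rows with VAS: 369  VAS cutoff: >=3
#> during-nursing performance (sens% / spec% / AUC / accuracy%):
#>   bps       84.95 /  53.33 / 0.70 /  77.24 (cutoff >= 4)
#>   cpot      84.95 /  46.67 / 0.68 /  75.61 (cutoff >= 1)
#>   combined  82.80 /  53.33 / 0.70 /  75.61 (cutoff >= 5)
#> BPS-CPOT severity agreement (quadratic kappa): before 0.33, during 0.77, after 0.72, overall 0.82
#> most discriminating item: cpot_facial (d = 1.63, very large)
```

Reading the output: during nursing the BPS flags pain (score ≥ 4) with
sensitivity 84.95 % and specificity 53.33 % against the patients' own
VAS ≥ 3 report, for a prevalence-weighted accuracy of 77.24 %; the two
instruments' severity gradings agree well (kappa > 0.6) during and
after the procedure; and facial expression is by far the most
responsive item (d = 1.63, "very large"), which is the expected
signature — the generator is calibrated so facial expression dominates.

Individual statistics are exported for library use, e.g.:

```r
spearman_rank_correlation(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))$estimate  # 0.8
quadratic_weighted_kappa(c(0, 1, 2, 1), c(0, 2, 2, 1))$kappa            # 0.8
best_cutoff_youden(roc_curve(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1)))$cutoff # 4
```

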