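# lmocc

Rule-based 12-lead ECG criteria for recognising **acute total left main
coronary artery (LM) occlusion** — a rare, often fatal culprit lesion whose
ECG presentation is notoriously heterogeneous — together with the
diagnostic-accuracy machinery needed to evaluate such criteria, and a
synthetic-cohort generator that makes every reported figure recomputable
without access to patient data.

The package is aimed at cardiology researchers and biostatisticians working
on ECG-based culprit-artery prediction: it provides the classification rules
as composable, testable code, and a fully reproducible six-group reference
cohort (552 patients) on which their operating characteristics can be
recomputed exactly.

## What it implements

**Lead-wise ST-elevation calls.** ST elevation (STE) in lead *ℓ* is called
when the deviation satisfies *st(ℓ) ≥ τ(ℓ, sex)* with τ = 2 mm (men) or
1.5 mm (women) in V2–V3 and 1 mm elsewhere (1 mm = 0.1 mV; boundaries
inclusive).

**The three-pattern taxonomy of LM occlusion**, with a finer 12-level
breakdown underneath:

1. *STEMI pattern* — ≥2 adjacent precordial leads (V1…V6), or ≥2 of
   II/III/aVF, or (V5∨V6) ∧ (I∨aVL);
2. *aVR pattern* — STE confined to aVR (± V1) with widespread ST depression
   (global subendocardial ischemia);
3. *aVR+aVL pattern* — STE in both aVR and aVL without V4–V6 involvement.

**Combined diagnostic criteria.** With S the set of elevated leads:

- **Model 1** = [aVR ∈ S ∧ aVL ∈ S] ∨ [{I, aVL, V2…V5} ⊆ S ∧ V1 ∉ S ∧ aVR ∉ S]
- **Model 2** = Model 1 ∧ LAFB (left anterior fascicular block, with or
  without RBBB)

**Diagnostics.** 2×2 contingency tables; sensitivity/specificity/PPV/NPV with
Wilson score intervals; Pearson chi-square (Fisher fallback for sparse 2×2
tables); one-way ANOVA; empirical ROC with tie-corrected AUC and the Youden
cutoff; the binormal closed-form AUC Φ((μ₊−μ₋)/√(σ₊²+σ₋²)) as an analytic
oracle.

**Synthetic cohort.** `simulate_cohort()` reconstructs the six-group study
cohort (84 LM occlusion / 89 LM subocclusion / 85 pLAD / 98 mLAD / 91 LCX /
105 RCA) *exactly* from the published marginal counts — every feature-table
row and every collateral-table cell is reproduced by classification of the
generated records — or samples arbitrary-size cohorts at the same joint
proportions. A small ECG beat synthesiser (`synthesize_beat()`,
`measure_st()`) grounds the millimetre measurement convention (J + 60 ms
vs the PR baseline) at signal level.

## Worked example

```r
library(lmocc)

cohort <- simulate_cohort(seed = 7)   # exact 552-record reconstruction
run_pipeline(cohort, criteria = c("ste_avr_avl", "i_avl_v2_v5",
                                  "model1", "model2"))
#> lmocc evaluation: 552 records; positive class lm_occlusion
#>   ste_avr_avl                sens  27%  spec  98%  (tp 23 fp 10 fn 61 tn 458)
#>   i_avl_v2_v5                sens  35%  spec  97%  (tp 29 fp 13 fn 55 tn 455)
#>   model1                     sens  62%  spec  95%  (tp 52 fp 23 fn 32 tn 445)
#>   model2                     sens  39%  spec  99%  (tp 33 fp 3 fn 51 tn 465)
```

Reading: of the 84 LM-occlusion patients, 52 meet Model 1 (sensitivity 62%)
at the cost of 23 false positives among the 468 controls (specificity 95%);
adding the fascicular-block requirement (Model 2) trades sensitivity (39%)
for near-perfect specificity (99%). The two Model-1 components are disjoint
by construction, so 23 + 29 = 52 exactly.

ROC of QRS duration (wider QRS favours LM occlusion):

```r
wide <- simulate_cohort(mode = "sampled",
                        n_per_group = c(84, 89, 85, 98, 91, 105), seed = 7)
glance(cohort_roc(wide))
#> # A tibble: 1 × 6
#>     auc youden_cutoff sens_at_cutoff spec_at_cutoff n_pos n_neg
#>   <dbl>         <dbl>          <dbl>          <dbl> <int> <int>
#> 1 0.747           105           0.75          0.684    84   468
```

`autoplot()` on the ROC object, `plot_criteria()` on an evaluation, and
`plot_pattern_counts()` on a classified cohort give the corresponding
ggplots; `tidy()`/`glance()` return tibbles throughout.

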