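# campusmh

Forecasting on-campus mental-health consultations from campus social-media
language.

University counseling services see monthly demand that swings with the
academic calendar and is hard to anticipate. The language students post on
their campus's online community — symptomatic expressions of depression,
anxiety, stress, suicidal ideation, and psychosis — is a candidate leading
indicator of that demand. `campusmh` is a tested R pipeline for evaluating
the idea end to end:

1. **Classify** posts with per-outcome n-gram (n = 1–3) linear SVMs
   (transfer design: outcome-community positives vs a general control
   corpus) and aggregate monthly expression prevalence.
2. **Relate** prevalence to the normalized consultation rate
   (100 × visits / enrollment): moving-window trend and period-12
   seasonality removal with augmented Dickey–Fuller verification, then
   lagged regressions of the consultation residual at month *t* on the
   expression residual at *t − lag*, controlling for both series'
   previous-month values; the standardized coefficient *e* is scanned over
   lags 0–6.
3. **Forecast** with seasonal ARIMA under anchored 10-fold rolling
   cross-validation: model **M0** (consultations only) vs **M1**
   (consultations + social-media covariates), compared by Pearson's r,
   MAE, and SMAPE = 100 · mean |y−x| / [(|y|+|x|)/2], a 1000-shuffle
   permutation null, and the Williams/Steiger t test for two dependent
   correlations sharing the actual series.
4. **Characterize** the language of high- vs low-consultation months
   (median split): salient n-grams via a from-scratch Sparse Additive
   Generative Model (SAGE, self-tuned sparsity), and `.dic`-lexicon
   category profiling with Welch t tests under Benjamini–Yekutieli FDR
   control.

Consultation records are confidential and campus post archives are not
redistributable, so a first-class synthetic-data module
(`make_calendar()`, `gen_consultations()`, `gen_posts()`,
`gen_training_corpora()`) generates both with the structure the analysis
assumes — academic-calendar seasonality, and a configurable coupling by
which symptom language *leads* consultations by a chosen lag. Every stage
also reads user data in plain formats (JSONL posts,
`month,visits,enrollment` CSV, `.dic` dictionaries).

See the methods vignette (`vignettes/campusmh-methods.Rmd`) for the models,
assumptions, and numerical choices.

## Worked example

A full synthetic study — 64 months, 12 posts/day, symptom language coupled
to consultations at lag 2 — classifiers trained, posts labeled, series
residualized, lags scanned, M0/M1 cross-validated, language profiled:

```r
library(campusmh)
cfg <- pipeline_config(
  seed = 7,
  sim = sim_config(seed = 7, n_months = 64, posts_per_day = 12,
                   coupling = 2, lag = 2),
  prevalence_from = "classifier", n_perm = 1000)
rep <- run_pipeline(cfg)
rep$best_lag
#>        depression           anxiety            stress suicidal_ideation
#>                 2                 2                 2                 2
#>         psychosis
#>                 2
print(rep)
```

```
Forecast comparison:
Model M0 (baseline):   Pearson's r = 0.751 | MAE = 0.837 | SMAPE = 9.74 (n = 52)
Model M1 (+ social):   Pearson's r = 0.863 | MAE = 0.629 | SMAPE = 7.56 (n = 52)
Relative improvement:  r +14.81%, SMAPE -22.39%
Dependent overlapping correlation: t = -3.13, df = 49, p = 0.002952
Permutation null (M1): 1000 permutations: mean r = -0.004, mean SMAPE = 21.28, P(better) = 0.0000

Top Hi-month terms:  lonely_uneasy, uneasy_anxious, is_worthless, ...
FDR-significant categories: negemo, posemo, anxiety, sadness, stressload, ...
```

Reading it: the lag scan recovers the planted two-month lead for every
outcome; adding the (lag-shifted, PC1-combined) social-media covariates
lifts the pooled cross-validated correlation from 0.75 to 0.86 and cuts
SMAPE by 22%; the dependent-correlation test says that difference is not
noise (t = −3.13, negative favoring M1); and no permutation of the
predictions beats the real model. The salience stage surfaces the symptom
lexicon n-grams that were planted into high-consultation months, and every
symptom-linked lexicon category is FDR-significant in the Hi-vs-Lo
comparison.

Classifier quality is reported per outcome
(`rep$classifier_accuracy`; held-out accuracy ≥ 0.99 on the default
separable corpora).

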