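---
title: "Methods: forecasting campus mental-health consultations from social-media language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting campus mental-health consultations from social-media language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campusmh)
```

## The problem

University counseling centers face demand they can rarely anticipate:
monthly consultation volume swings with the academic calendar, and staffing
decisions are made months ahead. The language students post on their
campus's online community is a candidate leading indicator — symptomatic
expressions of depression, anxiety, stress, suicidal ideation, and
psychosis wax and wane with the same academic pressures that drive
consultations. `campusmh` implements, as one tested pipeline, the chain of
analyses needed to evaluate that idea: classify posts for symptomatic
language, aggregate monthly prevalence, relate it to normalized
consultation rates at a range of lags, compare seasonal forecasting models
with and without the social-media signal, and characterize the language of
high- versus low-consultation months.

Real consultation records are confidential and campus post archives are not
redistributable, so the package carries a synthetic-data module that
generates both with the statistical structure the analysis assumes. All
tests and the worked examples run against that module; every stage accepts
user-supplied data in plain formats (JSONL posts, `month,visits,enrollment`
CSV, `.dic` lexicons) when the real thing is available.

## The synthetic study system

`make_calendar()` encodes the academic cycle as a period-12 seasonal load
(centered to mean zero over any 12 consecutive months) plus a slow linear
trend. Defaults place peaks in April, July, and November — the run-ups to
spring, summer, and fall examinations, with April the annual maximum — and
troughs in December, February, and October (holiday months). The seasonal
amplitude (2 percentage points at the main peak) and a monthly trend of
0.02 points are generator choices a campus health researcher would call
realistic against a baseline rate of 8% of enrolled students per month;
month-level Gaussian noise has SD 0.8 points, and rates are clipped at
zero.

`gen_consultations()` turns the calendar into the normalized monthly
consultation series. `gen_posts()` writes the coupled post stream: post
counts are Poisson per day (the simplest count model at the configured mean
of 33 posts/day), post lengths Poisson with mean 40 tokens, authors drawn
from a pool of 18,401. Each token comes either from a Zipf-weighted
background vocabulary or from one of five disjoint symptom lexicons. The
symptom share follows a multinomial logit: outcome *o*'s token share in
month *t* is

$$p_o(t) = \frac{b\,e^{\kappa z_{t+\ell}}}{1 + K b\,e^{\kappa z_{t+\ell}}},$$

where $z$ is the standardized consultation series, $\kappa$ the coupling,
$\ell$ the lead (posts lead consultations by $\ell$ months), $K = 5$ the
number of outcomes, and $b$ calibrated so the share equals `base_mix`
(3%) at $z = 0$. Setting $\kappa = 0$ makes the stream independent of the
consultation series by construction.

Two consequences of the logistic link are worth knowing. First, it keeps
shares in $(0, 1)$ under any coupling — the reason it was chosen. Second,
it saturates: the raw Pearson correlation between monthly lexicon
prevalence and the consultation series rises steeply with coupling and then
*flattens and slightly declines* (median ~0.98 at $\kappa = 0.5$, ~0.93 at
$\kappa = 2$ over ten seeds) because the compressed upper range leaves
proportionally more room for sampling noise. On the log-odds scale — the
scale on which the link is linear — the correlation is monotone in
$\kappa$, and that is how the test suite checks coupling monotonicity.

What the generator does *not* emulate: thread structure, author-level
dependence, vocabulary drift, markup, or any distributional feature of real
posts beyond token frequencies — the published study reports only corpus
totals, so anything finer would be invention. Passing tests therefore
demonstrate that the pipeline recovers structure *of this kind* when
present; they say nothing about classifier transfer quality on real campus
language.

## Symptom classifiers

`train_classifier()` fits one linear SVM per outcome on n-gram counts
(n = 1, 2, 3), mirroring the transfer design in which positive examples
come from an outcome-specific community and negatives from a general
control sample. Tokenization is deliberately minimal (lowercase, split on
non-alphanumerics, keep tokens of length >= 2) so results are easy to
reproduce; n-grams seen in fewer than two documents are pruned for
tractability (both knobs are arguments). Counts enter raw by default with
`1 + log(count)` weighting behind a flag. The decision threshold is the
SVM's natural zero margin — labels are meant to be used as hard 0/1 flags,
so no calibration is applied. Held-out accuracy on a stratified 20% split
is reported before the final refit on all documents; on the default
separable synthetic corpora (500 documents per class, lexicon-token rate
0.30 in positives vs 0.01 in negatives) it exceeds 0.95. A month with zero
posts yields a missing prevalence value with a warning; interpolation is
deferred to the series-building stage so the policy is applied exactly
once.

## Series building

Consultation counts are normalized to a percentage of enrollment.
Residualization removes a centered moving-average trend (default window 12
months — one academic year, matching the period of the known seasonality;
even windows use the standard 2×m weights) and a period-12 seasonal
component estimated as month-of-year means of the detrended series,
re-centered to sum to zero. The residual is defined as the remainder, so
the decomposition is additive by construction. Trend values at the edges,
where a centered average does not exist, are filled with the nearest
interior estimate; on a 64-month series, discarding a full window instead
would cost a fifth of the data. The cost of that choice is mild edge
leakage: residualizing a second time is exactly idempotent only when the
trend is flat, and on sloped input the first and last half-window of
residuals shift slightly (interior residuals correlate > 0.95 across
passes).

Stationarity of each residual series is verified with an augmented
Dickey–Fuller test (constant + trend regression; lagged-difference order
selected by AIC up to $\lfloor (n-1)^{1/3} \rfloor$ on a common sample;
p-values interpolated from the tabulated Dickey–Fuller distribution and
clamped to [0.01, 0.99]). The test is implemented in-package. A residual
that still fails the test warns rather than errors, and the report is
attached to the series.

`lagged_association()` regresses the consultation residual at month *t* on
the expression residual at *t − lag*, controlling for the previous month's
values of both series, everything standardized on the aligned sample so the
coefficient *e* is comparable across outcomes. The residual (not raw)
series are used for the controls for internal consistency. At lag 1 the
expression control *is* the predictor and is dropped. The default scan
range is 0–6 months.

## Forecasting

`fit_sarima()` wraps maximum-likelihood seasonal ARIMA with AIC selection
over a configurable order grid. The full grid (p, q, P, Q in 0–2; d, D in
0–1; period 12) is the default of `fit_sarima()` itself; the pipeline and
the simulation studies use the `"small"` preset (all orders 0–1), which on
series of 48–84 months almost always contains the selected model and is
about forty times cheaper — the methods here were sized to series of a few
dozen months, not to long archives.

Cross-validation is anchored and rolling: the first year is always
training; the remaining months are split into k = 10 contiguous blocks,
and each block is forecast by a model fit on everything before it. A
SARIMA likelihood cannot be evaluated on temporally disjoint training
segments, so "use the rest of the data" is realized as "use the past",
which also keeps every prediction a genuine forecast. Orders are selected
once on the full series by default (`order_search = "per_fold"` re-selects
per fold). When a fold's refit fails to converge — early folds can be
short — a chain of simpler seasonal models and finally a seasonal-naive
rule supplies the forecast, so the pooled prediction set always covers
every non-anchor month exactly once.

Model M0 uses the consultation series alone; M1 adds the monthly
expression prevalences of depression, anxiety, stress, and suicidal
ideation (psychosis is excluded by default, following the outcome set used
for the forecasting stage of the study design; it can be added via
configuration). Covariates follow a nowcasting contract — observed values
of the test months are supplied at prediction time — and are shifted
forward by each outcome's best scanned lag when that lag is positive,
which is precisely the regime in which a leading indicator helps. Because
the prevalence series measure overlapping constructs and are strongly
correlated (in the generator they share one latent load; in real data
symptom categories co-occur heavily), the pipeline collapses the shifted
covariates to their first principal component by default
(`exog_combine = "pc1"`); feeding several nearly collinear regressors to a
small-sample SARIMA demonstrably destabilizes fold refits, while the
one-dimensional summary improved cross-validated SMAPE on 10/10 seeds in
the package's own simulations.

Evaluation pools all fold predictions and reports Pearson's r, MAE, and
SMAPE $= 100 \cdot \mathrm{mean}\,|y-x| / [(|y|+|x|)/2]$, with a term
defined as 0 when both sides are 0 (continuity of the limit). Note the /2
convention: this form is bounded by 200, not 100 — each term stays below 1
exactly when prediction and actual agree within a factor of three, which
is why workable forecasts report values in the familiar 0–100 range; the
test suite asserts exactly that distinction. Model
comparison reports the relative gain in r and reduction in SMAPE, the
Williams/Steiger t for two dependent correlations sharing the actual
series (signed baseline-minus-augmented, so negative favors M1), and a
permutation null: predictions shuffled over months 1000 times, with the
fraction of permutations beating the real model (higher r *and* lower
SMAPE) reported.

## Language of high- and low-consultation months

Months are median-split on the normalized rate; ties at the median
alternate into whichever group is smaller, honoring the near-balance a
median split implies. Each group's posts form a corpus.

Salient n-grams come from a from-scratch Sparse Additive Generative Model:
the Hi-month corpus is modeled as $p(w) \propto \exp(m_w + \eta_w)$ with
$m$ the log relative frequencies of the Lo-month (background) corpus
(smoothed by 0.5) — a direct Hi-vs-Lo contrast, matching the single signed
salience axis the analysis reports. The penalized likelihood is maximized
by damped diagonal proximal-Newton steps; convergence requires the largest
coordinate change to fall below 1e-6 (500-iteration cap, error with
diagnostics beyond it). The default regularization is self-tuned: each
term carries penalty $\eta_w^2 / 2\tau_w$ with $\tau_w = \eta_w^2 +
\epsilon^2$ re-estimated every iteration — a majorization scheme for a log
penalty under which strong deviations are left nearly free while weak ones
are driven to zero. Because zero is a local attractor of that penalty, the
optimizer warm-starts at the unpenalized estimate rather than at zero. A
fixed L1 mode (`reg = lambda`) exposes the classical penalized objective —
it is the mode checked against a brute-force coordinate-grid maximizer in
the tests — and `reg = 0` returns the closed-form smoothed log-ratio, with
the gauge fixed by $Z = 1$ (the likelihood is invariant to adding a
constant to every $\eta_w$; an optional background-weighted zero-sum gauge
is available instead). Ranking ties break by background frequency, then
lexicographically.

Psycholinguistic profiling reads any `.dic`-dialect dictionary (category
header block, word lines, terminal-`*` prefix wildcards). The proprietary
50-category instrument used in the study cannot ship, so the package
includes a small open demonstration lexicon (12 categories built around the
synthetic symptom lexicons plus everyday campus vocabulary); analyses of
real data should supply a real dictionary file. Per document, each
category's occurrence is normalized to a percentage of tokens; groups are
compared by Welch t tests per category (signed Hi − Lo), adjusted by the
Benjamini–Yekutieli step-up procedure — the arbitrary-dependence variant
with the harmonic-number factor, the conservative reading of the study's
"Benjamini-Hochberg-Yekutieli" correction — with plain BH behind a flag.
The unit of analysis is the per-document percentage; per-month aggregation
can be had by profiling month-concatenated documents.

## Orchestration and reproducibility

`run_pipeline()` sequences simulate/ingest → train → label → analyze →
forecast → salience from a single `pipeline_config()` (YAML-loadable via
`read_pipeline_config()`), halts with a stage-tagged error on failure, and
returns a consolidated report whose JSON/CSV artifacts are byte-identical
across runs with the same seed. The global seed fans out to stages by fixed
offsets (simulation +0, classifier split +11, permutations +23) so a stage
can be re-run in isolation. For speed, the pipeline can compute prevalence
directly from symptom-lexicon token frequency (`prevalence_from =
"lexicon"`) instead of training and applying classifiers; the classifier
path is the default.

## Numerical choices and limitations

* Problem sizes in the tests and the acceptance script: 40–64-month
  series, 5–33 posts/day, 10–20 seeds per property, the small order grid,
  200–1000 permutations. These sizes were chosen so each simulation study
  is stable at the asserted thresholds while a full run stays comfortably
  interactive.
* The ADF p-value is interpolated from tabulated quantiles, so it is
  clamped to [0.01, 0.99]; verdicts at conventional levels are unaffected.
* `stats::arima` occasionally fails to converge on short seasonal
  training windows; the fallback chain trades model fidelity for coverage
  of every fold and is reported through the selected-orders field.
* The SMAPE /2 convention, its true [0, 200] bound, and the edge effects
  of the moving-average trend are discussed above; both are deliberate,
  documented departures from folklore claims that do not survive
  arithmetic.
* Classifier accuracy on synthetic corpora is an upper bound on nothing:
  the corpora are separable by construction. The number demonstrates the
  training path works, not that transfer to real campus language would
  reach the same level.
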