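# fibroscore

Quantitative image features and a lasso **Fibrosis Score** for systemic
sclerosis (SSc) skin biopsies, with the accompanying histopathology
statistics — all testable end-to-end on synthetic data.

## The problem

The modified Rodnan skin score (mRSS; 0–3 at 17 body sites, total 0–51)
is the clinical standard for SSc skin disease but measures thickness
only, by palpation. An image-based alternative works from the biopsy
itself: sample random dermal patches from a trichrome-stained section,
map each patch to a vector of quantitative image features (QIFs), and
predict mRSS per patch with a penalized linear model,

&nbsp;&nbsp;&nbsp;&nbsp;minimize&nbsp;
½ · mean((y − β₀ − Xβ)²) + λ‖β‖₁,

training on patches that carry their biopsy's mRSS. The per-biopsy
**Fibrosis Score** is the mean of the patch predictions. λ is chosen
from 16 log-spaced values in [10⁻⁵, 10³] by grouped cross-validation
that holds out whole patients, so within-patient correlation never leaks
across folds. The package is aimed at researchers developing
image-based skin outcomes who need a fully specified, reproducible
reference pipeline plus the statistics used to interpret such a score:

* **Cohen's kappa** (unweighted, with the standard six agreement bands)
  for inter- and intra-rater agreement on a 16-parameter
  dermatopathology schema;
* **proportional-odds ordinal regression** — cumulative-logit MLE by
  Newton iterations, Wald inference, OR = exp(β) with OR > 1 meaning
  higher categories at larger predictor values;
* **random-intercept + random-slope mixed models** (independent
  covariance, REML) for per-week change of each parameter;
* **Spearman rank correlation** with exact small-sample permutation p.

No patient data for this problem are public, so the synthetic-data
module is first-class: trichrome-like slides with a planted severity
(the blue-collagen pixel fraction is 0.2 + 0.5·severity), longitudinal
cohorts with baseline mRSS in the 15–40 eligibility band, two simulated
raters with controllable agreement, and proportional-odds ordinal
outcomes. Every planted quantity is recoverable, and the tests prove it.

## Worked example

```r
library(fibroscore)

# a small synthetic cohort: 6 patients, biopsies at weeks 0/24/52
coh <- generate_cohort(6, seed = 7)
coh$biopsy_id <- sprintf("%s_W%02d", coh$patient_id, coh$week)

# render a slide per biopsy, sample dermal patches, extract features
be <- make_backend("texture32")
qifs <- lapply(seq_len(nrow(coh)), function(i) {
  sl <- render_biopsy_slide(coh$severity[i], mpp = 2, height_px = 360,
                            width_px = 480, seed = 100 + i,
                            min_patch_px = 100)
  ps <- sample_patches(sl, sl$mask, n = 10, area_mm2 = 0.04,
                       seed = 200 + i, biopsy_id = coh$biopsy_id[i])
  extract_qif(sl, ps, be)
})

# fit the Fibrosis Score model with grouped-CV penalty selection
model <- fit_fibrosis(qifs,
                      labels = setNames(coh$mrss, coh$biopsy_id),
                      groups = setNames(coh$patient_id, coh$biopsy_id),
                      seed = 1)
print(model)
#> Fibrosis Score lasso model: 32 features, 5 nonzero, lambda = 0.1848
#> intercept (training-mean mRSS): 29.833
#> lambda selected by 6-fold grouped CV (min MSE 8.525)

predict(model, qifs[[1]])
#> <fibrosis_score> P001_W00: 41.275 (mean of 10 patch predictions)

evaluate_scores(lapply(qifs, predict_fibrosis_score, model = model),
                coh$mrss)
#> Spearman rho = 0.966, p = 7.335e-11 (n = 18, t approximation)
```

The printed model says 5 of 32 texture features survived the selected
penalty (λ ≈ 0.18, an interior grid point chosen by cross-validation);
the intercept is the training-mean mRSS, so a fully penalized model
would predict that constant. The score for the first biopsy (41.3, a
high-severity baseline biopsy) is the mean of its 10 patch-level mRSS
predictions, and the in-sample Spearman correlation between scores and
the true mRSS labels is 0.97.

The statistics layer works on score sheets:

```r
d <- simulate_proportional_odds_data(beta = log(2), n = 5000,
                                     k_categories = 2, thresholds = 0,
                                     x_sd = 2, seed = 1)
fit_proportional_odds(d$y, d$x)
#> proportional odds: OR = 1.997 [1.913, 2.084], p = 1.055e-220 (n = 5000, 2 categories)
```

A planted odds ratio of 2 is recovered as 1.997 with a tight Wald
interval — the same recovery logic the acceptance script uses.

`run_pipeline(config, outdir)` chains all stages (simulate → sample →
extract → fit → score → stats) from a YAML config and writes
`scores.csv`, `or_table.csv`, `kappa_table.csv`, `slopes.csv`,
`correlation.json`, `model.json` and a `manifest.json` with file hashes;
two runs with the same config are byte-identical.

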