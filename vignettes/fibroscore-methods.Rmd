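---
title: "Methods: the Fibrosis Score pipeline and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Fibrosis Score pipeline and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Systemic sclerosis (SSc) skin disease is scored clinically with the
modified Rodnan skin score (mRSS), a semi-quantitative palpation exam
(0–3 at 17 sites, total 0–51) that measures thickness only. `fibroscore`
implements an image-based alternative: random dermal patches from a
trichrome-stained biopsy section are mapped to quantitative image
features (QIFs), a penalized linear model predicts mRSS from each patch,
and the per-biopsy **Fibrosis Score** is the mean of the patch
predictions. Around this core the package implements the statistics used
to interpret such a score against conventional dermatopathology: Cohen's
kappa for rater agreement, proportional-odds ordinal regression for
histological odds ratios, a random-intercept-and-slope mixed model for
per-week change, and Spearman rank correlation.

Because no public patient data exist for this problem, the package treats
the synthetic-data generator as a first-class module: every downstream
stage is specified, tested and exercised against planted ground truth.

## Patch sampling

Patches are axis-aligned squares of side $\sqrt{A}$ (default
$A = 0.16\ \mathrm{mm}^2$, i.e. a 400 µm square; 200 px at the default
calibration of 2 µm/px). Centers are drawn uniformly at random **with
replacement** — overlap is allowed — from positions whose entire
footprint carries the dermis label; epidermis and subcutis are excluded
strictly, with no partial-tissue patches. Coordinates are 0-based
`(row, col)` half-open squares. Feasibility of a candidate corner is an
O(1) lookup in a summed-area table of the dermis indicator; after
$1000 \cdot n$ rejected candidates the sampler raises a typed
`sampling_exhausted_error` reporting how many patches were placed, and it
distinguishes that case from a mask with no valid position at all
(`no_dermis_error`). Uniformity over the valid corner set is tested by a
chi-square goodness-of-fit on 10,000 draws.

Dermis delineation itself is out of scope: the pipeline requires a
compartment mask as input (the synthetic renderer emits one), using the
label convention 0 = background, 1 = epidermis, 2 = dermis, 3 = subcutis.

## Feature backends

Two interchangeable backends produce the patch-by-feature QIF matrix.

**`texture32`** is a deterministic 32-dimensional stain/texture
descriptor, used for all statistical work in the package's tests. Order
and definitions are fixed: per stain channel after optical-density color
deconvolution with a fixed trichrome matrix (unit OD vectors for aniline
blue `(0.80, 0.59, 0.11)`, red counterstain `(0.10, 0.74, 0.67)` and
hematoxylin `(0.65, 0.70, 0.29)`, rows normalized) — mean, sd, q10, q50,
q90 (15 features); collagen-channel area fraction above OD 0.10 (1);
per-stain gradient-magnitude mean and sd (6); grey-level co-occurrence
contrast, homogeneity, energy (angular second moment) and correlation at
offsets (0,1) and (1,0) on a fixed 16-level quantization of [0,1] (8);
bright-object (lumen/fat, luminance > 0.88) pixel fraction and connected
components per 1000 px (2). GLCM correlation is defined as 0 when a
marginal standard deviation vanishes, so constant patches are
well-defined. The GLCM implementation is verified against a brute-force
co-occurrence tally in the tests. Per-slide stain recalibration is a
non-goal; the matrix is a configuration constant.

**`cnn4096`** reproduces the *shape* of the classical five-convolution /
two-4096-unit fully-connected feature extractor with seeded
He-initialized random weights (227×227 input, ungrouped filter banks of
96/256/384/384/256, 3×3/2 max-pooling, no local response normalization).
Patches are bilinearly resized and channel-normalized with the fixed
constants mean (0.485, 0.456, 0.406), sd (0.229, 0.224, 0.225). The
reported 4096-vector is the penultimate fully-connected activation;
`layer = "fc6"` or `"fc7"` (default) selects which of the two 4096-unit
layers, a genuinely open choice since either is defensible. Random
convolutional features preserve the 100 × 4096 matrix contract and all
pipeline plumbing without any download; they are weaker than pretrained
features, which is why the statistical acceptance work uses `texture32`.
Loading pretrained weights is not supported: no ONNX runtime exists for
this R toolchain, and shipping one is out of scope.

## The Fibrosis Score model

Training rows are patches, each carrying its biopsy's mRSS label (the
model predicts per patch; averaging to the biopsy happens after
prediction). Features are standardized to mean 0, sd 1 **on the training
rows only**; held-out patches reuse the training means/sds, preventing
leakage. The coefficients minimize

$$\tfrac12\,\overline{(y - \beta_0 - X\beta)^2} + \lambda \lVert\beta\rVert_1$$

with an unpenalized intercept — which therefore equals the training-mean
mRSS whenever the penalty kills every coefficient. The solver is cyclic
coordinate descent in the covariance (Gram-matrix) formulation:
convergence when the largest coefficient change in a sweep falls below
1e-7, at most 10,000 sweeps; constant features are dropped with a warning
and reported with coefficient 0. The solver is cross-checked in the tests
against an independent lasso implementation and, at $\lambda = 0$,
against the normal equations.

$\lambda$ comes from a 16-point grid, log-spaced from $10^{-5}$ to
$10^{3}$. Selection is by grouped cross-validation: folds hold out whole
patients (leave-one-patient-out up to 10 patients, 5 seeded grouped folds
beyond), the held-out loss is the squared error of the *biopsy-level*
score against its label, and exact ties (within 1e-12) resolve to the
larger, more parsimonious penalty. The criterion (minimum mean squared
error) and the tie-break are the package's choices; train/test patient
disjointness is asserted programmatically inside every fold. After
selection the final model is refitted on all patients at $\lambda^\*$ —
whether to refit was an open choice; refitting uses all information and
is recorded here. Scores are reported unclipped even though they
approximate the 0–51 mRSS scale.

## The statistics layer

**Cohen's kappa** is unweighted,
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal products,
with the standard six agreement bands (≤ 0 no agreement; 0.01–0.20 none
to slight; 0.21–0.40 fair; 0.41–0.60 moderate; 0.61–0.80 substantial;
0.81–1.00 almost perfect). Two conventions needed fixing: the open gap
(0, 0.01) is assigned to "none to slight", and continuous parameters
(thickness in µm, cell densities, percentages) are discretized into
quintile bins before kappa — the band definitions presuppose categorical
ratings and no binning rule is standard, so the choice is documented
here. Both raters constant on the same category makes $p_e = 1$ and
kappa undefined; that is a typed error, and the agreement table reports
such parameters as NA.

**Proportional odds.** The cumulative-logit model is parameterized as
$P(Y \le k \mid x) = \mathrm{logistic}(\theta_k - \beta x)$, so
$e^{\beta} > 1$ means a unit increase in the predictor raises the odds
of a *higher* category — the interpretation convention used for
odds-ratio tables in this field; software conventions differ, hence the
explicit statement. Fitting is full Newton with analytic gradient and
Hessian, step-halving, convergence at gradient norm < 1e-8; inference is
Wald from the observed information (95% CI $e^{\beta \pm 1.96\,SE}$),
with no profile-likelihood option and — deliberately mirroring an
exploratory design — no multiplicity correction at $\alpha = 0.05$.
Diverging $|\hat\beta|$ (quasi-separation) raises a typed error with
guidance rather than returning a meaningless estimate. With two
categories the fit coincides with binary logistic regression to 1e-6
(tested against an independent MLE). In the odds-ratio table, binary
parameters reduce to logistic regression and continuous parameters are
rounded to integers and fitted as reported-scale ordinal responses.

**Per-week change.** Each parameter is averaged over raters and sessions
per biopsy and fitted with
$y_{ij} = \beta_0 + \beta_1 w_{ij} + u_{0i} + u_{1i} w_{ij} +
\varepsilon_{ij}$, independent random effects (diagonal G, no
intercept–slope covariance), by restricted maximum likelihood: $\beta$
and the residual variance are profiled out in closed form per block, and
the two variance *ratios* are optimized on the log scale by Nelder–Mead.
Because the ratios are exponentials of unconstrained parameters, a
negative-variance iterate cannot occur; a ratio driven to the lower edge
of the search region is reported as a zero variance component, which is
exactly what happens on noiseless data. The implementation reproduces an
independent REML fit to about 1e-5 in the tests, and the tests also check
that the returned REML log-likelihood dominates a grid of other
admissible variance values.

**Spearman correlation** is the Pearson correlation of average ranks
(midranks under ties); the p-value uses the $t$ approximation on $n - 2$
degrees of freedom, switching to an exact two-sided permutation null for
$n \le 8$.

## The synthetic-data generator

The generator defines the study conditions and is not a tuning knob.

*Cohort.* Baseline mRSS sits in the diffuse-cutaneous trial eligibility
band 15–40 through the monotone link
`mrss = round(15 + 25*severity) + noise` (the link itself is a modelling
choice; any monotone link supports the recovery tests). Visits are weeks
0, 24, 52; per-patient slopes are Normal with sd 0.1 mRSS/week so 52-week
changes mostly span roughly ±10 units, matching the spread reported for
early diffuse-cutaneous trial cohorts; measurement noise (sd 1, rounded)
keeps scores integer. All mRSS are clipped to 0–51.

*Slides.* Rendering is deliberately stylized — a three-band geometry
inside a white border, oriented fiber texture from anisotropically
filtered white noise, fixed blue/red color anchors — because the
pipeline's acceptance surface is statistical, not photorealistic. The one
load-bearing property is the severity link: the blue-collagen pixel
fraction equals $0.2 + 0.5\,s$ plus a small seeded jitter, imposed by
quantile thresholding, so it is exactly monotone in severity at fixed
seed. Severity also thins the epidermis, raises the
inflammatory-infiltrate and vessel counts, and depletes subcutaneous fat
vacuoles. Defaults are 2 µm/px and 2048 × 3072 px so that one hundred
0.16 mm² patches fit comfortably. What the renderer does *not* emulate —
stain batch effects, scanner noise, real collagen morphology, IHC
chromogens — bounds what passing tests mean: they demonstrate correct
mechanics and statistical recovery under a known monotone link, not
performance on real slides.

*Raters.* True categorical scores derive from the planted parameters by
fixed monotone thresholds (e.g. subcutaneous fat loss iff severity > 0.5;
telangiectasia iff at least 3 ectatic vessel profiles; hyalinized
collagen $=\lfloor 6s \rfloor$ capped at 5). A rater profile perturbs
them: binary flips with probability < 0.5, ±1 jitter on 0–5 scales,
multiplicative noise at a given CV on continuous measurements, and an
optional extra drift at the second scoring session (the wash-out
re-read). Two independent raters with flip probability $q$ disagree with
probability $2q(1-q)$, which the tests verify empirically.

*Ordinal outcomes.* `simulate_proportional_odds_data` draws
$x \sim N(0, \sigma_x)$ and samples $Y$ from the cumulative-logit model
by inverse CDF; refitting recovers the planted coefficient within
simulation error, which is the basis of the odds-ratio recovery checks
(planted sizes 2.01 and 1.47 on binary outcomes and 1.10 on a 6-category
outcome, n = 5000, recovered within 3 standard errors).

## Numerical and scale choices

* Problem sizes in the test suite are chosen for desk-scale runtimes:
  the held-out-recovery check renders 60 biopsies (20 patients × 3
  visits) at 512 × 768 px with 20 patches per biopsy; the pipeline
  determinism check uses 5 patients at 320 × 448 px with 6 patches. The
  observed held-out Spearman correlation with planted severity (~0.99)
  leaves a wide margin over the 0.6 acceptance bound, so the reduced
  raster costs no statistical headroom.
* All randomness is scoped: generators take explicit seeds, restore the
  caller's RNG state, and the pipeline fans one run seed out to fixed
  per-stage child seeds, making every stage independently reproducible
  and full runs byte-identical.
* Slide calibration travels in a `.mpp.json` sidecar for both TIFF and
  PNG (the TIFF writer in this toolchain cannot embed resolution tags);
  a missing calibration with no explicit `mpp` is a typed error, never a
  guessed default.
* Zarr containers are not supported (no R implementation available);
  TIFF and PNG cover the slide I/O contract, and the format-equivalence
  test compares a TIFF/PNG twin pair.

## Known limitations

Random-weight convolutional features are a shape-faithful stand-in, not
a pretrained extractor; conclusions about real trichrome sections
require real weights and real slides. The renderer's monotone
severity→collagen link makes recovery easier than real histology, where
the link is noisy and confounded by staining variation. Ordinal fits use
Wald inference only, which is known to be optimistic near separation;
the separation guard raises an error rather than switching to penalized
estimation. The mixed model fixes the random-effects covariance to
diagonal by design and does not offer small-sample degrees-of-freedom
corrections.
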