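---
title: "Scoring and predicting intrinsic capacity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and predicting intrinsic capacity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icapacity)
```

## The problem

Intrinsic capacity (IC) is the WHO's composite of an individual's physical
and mental capacities, assessed in five domains: locomotion, sensory,
psychological, cognition and vitality. Integrated-care platforms for older
adults monitor these domains from questionnaires and simple measurements,
and — given longitudinal panel data — can predict where each domain is
heading. This package implements that computational core: domain scoring,
preprocessing, longitudinal dataset construction, and a four-family
regression benchmark under 10-fold cross-validation, together with a
synthetic cohort generator so the whole pipeline can be exercised and
tested without access to restricted panel data.

## Domain scoring

Each domain maps a standard instrument onto $[0, 1]$ (higher is better):

* **Locomotion** — Short Physical Performance Battery (balance, gait
  speed, chair stands; 0–4 points each): $\mathrm{IC} =
  \mathrm{SPPB}/\max(\mathrm{SPPB})$. The maximum is written abstractly in
  the source formulation; we use the standard instrument maximum of 12 and
  expose it as a configurable constant (`ic_constants()`).
* **Vitality** — $\min\{0.13\,(6 - \mathrm{SF12}_{10}) + 0.09\,
  \mathrm{Grip}_{kg},\; 1\}$. The SF-12 energy item is coded 1 = most
  energetic … 6 = least, so $(6 - \text{answer})$ rewards energy. Grip
  strength enters in raw kilograms as published: about 11 kg alone already
  saturates the score, so the cap at 1 binds for most adults with a grip
  measurement. We deliberately do **not** renormalize — fidelity to the
  published composite over statistical elegance — and flag the saturation
  here and in the function documentation.
* **Psychology** — PHQ-9 severity bands: 1.00 (0–4), 0.75 (5–9),
  0.50 (10–14), 0.25 (15–19), then $(27 - \mathrm{PHQ})/32$ above 19 so
  the score falls linearly to 0 at the instrument maximum.
* **Cognition** — MOCA total over its maximum of 30 (configurable, as for
  SPPB).
* **Sensory** — mean of four 1–5 self-ratings (hearing left/right, vision
  far/near), i.e. their sum over 20.

Instrument totals are integer-scored; non-integer totals are rejected
rather than rounded, since a fractional PHQ-9 or SPPB total indicates an
upstream data error, and the psychology bands are defined on integers.
A missing instrument yields an *unavailable* score (`NA`), never an
imputed one: scores are updated only when relevant new data exist. The
assessment cadence (daily vs weekly refresh) is not modeled; scoring is a
pure function of the latest available inputs.

There is deliberately no total-IC aggregate anywhere in the package — no
standardized formula for an overall IC amount exists — so profile exports
carry five axes and availability flags only.

## Preprocessing and the feature dictionary

Model inputs follow a fixed variable dictionary
(`ic_data_dictionary()`): ordinal and continuous variables are min–max
scaled to $[0,1]$ using *instrument-defined* bounds (never observed
minima/maxima, so the transform is dataset-independent); marital status —
the only non-quantitative categorical — is one-hot encoded with a full
(non-dropped) six-category list; and the cognition and depression totals
are z-scored with literature constants (MOCA mean 23.25, SD 4.82; PHQ-9
mean 5.79, SD 5.8) because different studies measure these constructs
with differently scaled instruments. Z-scores are not re-clipped: feature
vectors are mixed-scale by design.

The per-domain feature-vector lengths are pinned at 48 (locomotion),
43 (sensory, psychology, cognition) and 44 (vitality). The exact
decomposition behind these published input sizes is not printed anywhere,
so the dictionary realizes them with two defensible choices: six marital
categories (the civil-status breakdown typical of European panel
studies), and a five-entry locomotion block — the three SPPB point scores
plus the two raw timings (gait seconds, chair-stand seconds) that
panel studies record alongside them. Grip strength (vitality) and the
SPPB block (locomotion) appear only in their own domains because
examiner-administered measurements are missing for many participants,
which would otherwise shrink every domain's dataset.

Feature imputation defaults to column means (column-median and
drop-incomplete are available); **labels are never imputed** — a pair
whose label instruments are missing is dropped. Missingness is evaluated
on features *after* imputation and on labels *before* any imputation.

## Wave pairing

Waves are two calendar years apart. A supervised example pairs the
preprocessed features of subject $i$ at wave $t$ with the IC label of one
domain computed from the same subject's answers at wave $t + h$. The
horizon is $h = 2$ waves (four years) for locomotion and vitality —
their measurements recur only every other wave — and $h = 1$ otherwise.
Two further choices were genuinely open:

* *Sliding pairs*: every eligible wave $t$ emits an example, not just one
  pair per subject. This matches the magnitude of published dataset sizes
  relative to cohort size.
* *Strict horizon*: if wave $t+h$ is absent but some later wave exists,
  no example is emitted, keeping the prediction horizon homogeneous.

With $n$ fully observed subjects and $w$ waves this gives exactly
$n(w-1)$ examples at $h=1$ and $n(w-2)$ at $h=2$ — a closed form the test
suite checks — and it makes the longer-horizon domains never out-count
the short-horizon ones under uniform missingness.

## The synthetic cohort

The generator (`simulate_cohort()`) is a latent-trait model: each subject
draws one baseline trait per domain from a Beta(6, 2.5) (mean ≈ 0.7,
left-skewed — most older adults near the top of the range), which
declines by a per-domain per-wave amount (defaults 0.02–0.04 on the unit
scale, i.e. a few percent of capacity per two years) with small
wave-to-wave jitter (SD 0.03). Instruments are emitted from the latents
through the *inverse* direction of the scoring maps plus observation
noise, rounded and clamped to instrument ranges; generic questionnaire
items are driven by the relevant latent (loneliness by the psychology
latent, functional-independence items by locomotion, and so on). This
construction — rather than resampling marginals — guarantees the one
property the prediction harness needs: cross-wave predictability exists
by construction, so a working pipeline must find it.

Missingness is MCAR per instrument. The published mechanism (SPPB and
grip strength had to be administered by qualified personnel) is
documented but its rates are not, so the defaults are 0.5 for grip and
for the SPPB block (which goes missing as a unit — one examination) and
0.05 elsewhere. Dropout is 5% per wave, permanent. Ages advance exactly
two years per wave.

What a green test does **not** establish: the generator makes no attempt
to match any real study's marginal distributions, attrition patterns,
survey design, or the published benchmark metric values, which belong to
a registered external dataset. Green acceptance means the machinery is
correct on a world where truth is known, not that real-data accuracies
are reproduced.

`plant_linear_signal()` goes one step further for parameter recovery: it
replaces the label with a *known* linear function of the current-wave
preprocessed features plus Gaussian noise, clipped to $[0,1]$ (a mild
attenuation at the boundaries; the shipped coefficient sets keep labels
well inside the interval so the clip almost never binds). It emits a
ready feature-label dataset rather than a raw wave table, because
planting an exact linear label through the inverse of the piecewise
scoring maps is not well-defined once rounding and clamps intervene.

## The prediction harness

Four families, all implemented in-package (the usual R model packages
are not assumed):

* **Linear** — ordinary least squares via QR; aliased columns (the full
  one-hot block plus intercept) get zero coefficients.
* **Random forest** — bootstrap-aggregated CART regression trees
  (exact SSE split search in C++), `mtry = p/3`, deep trees, minimum
  node size 5.
* **Gradient boosting** — depth-3 CART trees on residuals, shrinkage
  0.1, squared loss.
* **Dense network** — hidden widths per domain (32-32-32-32 for
  locomotion; 16-16-16-16 for sensory and psychology; 16-32-16 for
  cognition; 8-16-16-8 for vitality), ReLU activations each followed by
  batch normalization, one linear output unit. Trained with Adam
  (lr $10^{-3}$), batch size 64, up to 200 epochs, early stopping
  (patience 20) on a 10% validation split, MSE loss. These training
  hyperparameters are package defaults, not published claims. One
  numerical choice that matters: batch-norm keeps hidden activations at
  unit scale while IC targets have SD well below 1, so the output layer
  is initialized small (SD 0.01) with its bias at the training-label
  mean; without this the optimizer spends most of its budget shrinking
  the regression head.

Tree ensemble sizes come from the grid {10, 50, 100, 200, 300, 500}.
Predictions are clipped to $[0,1]$, since IC lives there by definition.

Evaluation is k-fold cross-validation (default $k = 10$): one shuffle
with the given seed, then $k$ near-equal contiguous folds; metrics (MSE,
MAE, $R^2$, MedAE) are computed per fold on both the held-out fold and
the training portion, and averaged arithmetically. Train metrics are
fold-averaged (whether published train metrics came from fold averages or
a final full-data fit is not stated; fold-averaging keeps test and train
numbers on the same footing). $R^2$ on a constant-target fold is
undefined; it is reported as `NaN` and excluded from the average with a
warning rather than silently zeroed.

## Numerical and degenerate-input choices

* Scoring rejects out-of-range and non-integer instrument totals with
  classed range errors naming the offending field.
* Tie-break in CART split search: the first feature achieving the best
  gain wins; thresholds are midpoints between adjacent distinct values;
  splits that cannot move any row (numeric ties) fall back to a leaf.
* `kfold_cv` requires $2 \le k \le n$; batch normalization skips
  single-example remainders of a mini-batch shuffle.
* Seeds: every stochastic step (simulation, label noise, shuffling,
  bootstraps, weight init) is seeded, and seeding is local — library
  calls do not perturb the caller's RNG stream. Label noise uses
  `seed + 1` so it is independent of the cohort draw at the same seed.

## Known limitations

* The vitality formula's saturation means simulated vitality labels
  concentrate near 1 for subjects with any realistic grip strength;
  benchmarking on natural (non-planted) vitality labels therefore has
  little variance to explain. This mirrors the published composite, not a
  bug.
* MCAR missingness is a simplification; real panel attrition is
  informative.
* The in-package NN is a small, exact implementation adequate for these
  architectures; it is not a general deep-learning framework.
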