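# icapacity

Scoring and longitudinal prediction of **intrinsic capacity (IC)** — the
WHO composite of an older adult's physical and mental capacities — for
biostatisticians and digital-health engineers working with multi-wave
panel data.

The package covers four things:

1. **Domain scoring.** Five unit-interval scores from standard geriatric
   instruments:
   - locomotion: IC = SPPB / 12 (Short Physical Performance Battery);
   - sensory: IC = (H_left + H_right + V_far + V_near) / 20
     (1–5 self-ratings);
   - psychology: PHQ-9 severity bands 1.00 / 0.75 / 0.50 / 0.25, then
     (27 − PHQ)/32 above 19;
   - cognition: IC = MOCA / 30;
   - vitality: IC = min(0.13·(6 − SF12₁₀) + 0.09·Grip_kg, 1).

   Missing instruments give *unavailable* (never imputed) scores.
2. **Dataset construction.** Wave-t features paired with wave-(t+h) IC
   labels (h = 2 waves ≈ 4 years for locomotion/vitality, else 1 wave ≈
   2 years), with instrument-bound unit scaling, a marital-status
   one-hot, and literature z-scoring of MOCA (23.25/4.82) and PHQ-9
   (5.79/5.8) totals. Labels are never imputed; incomplete pairs drop.
3. **Model benchmark.** Linear regression, random forest, gradient
   boosting and a per-domain batch-norm dense network, all in-package,
   evaluated by 10-fold cross-validation with MSE / MAE / R² / MedAE on
   test and train partitions.
4. **Synthetic cohorts.** A latent-trait generator with per-domain
   decline, instrument noise, elevated missingness for
   examiner-administered measurements (grip, SPPB) and dropout, plus a
   planted-linear-signal mode for parameter-recovery checks.

See `vignettes/intrinsic-capacity-methods.Rmd` for the model details and
design rationale.

## Worked example

```r
library(icapacity)

# score one subject-wave record
prof <- compute_profile(list(
  sppb_balance = 3, sppb_gait = 4, sppb_chair = 3,
  hear_left = 4, hear_right = 4, vision_far = 3, vision_near = 4,
  phq9_total = 7, moca_total = 24, sf12_q10 = 3, grip_kg = 24
))
print(prof)
#> Intrinsic-capacity profile (0-1; NA = unavailable)
#>   locomotion  0.8333
#>   sensory     0.75
#>   psychology  0.75
#>   cognition   0.8
#>   vitality    1
```

Locomotion is 10/12 SPPB points; psychology 0.75 is the second PHQ-9
severity band (total 5–9); vitality saturates at 1 because 24 kg of grip
strength alone exceeds the composite's cap.

```r
# simulate a cohort, build the cognition dataset, benchmark a forest
tab <- simulate_cohort(cohort_config(n_subjects = 400, n_waves = 4, seed = 1))
ds  <- pair_waves(tab, "cognition")
summarize_dataset(ds)[c("n_examples", "label_mean")]
#> $n_examples
#> [1] 1033
#> $label_mean
#> [1] 0.6550823

kfold_cv(model_spec("random_forest", tree_count = 100, seed = 1),
         ds, k = 10, seed = 1)
#> 10-fold CV of Random Forest (trees = 100) (seed 1)
#>   test  MSE 0.0081  MAE 0.0694  R2 0.6897  MedAE 0.0539
#>   train MSE 0.0031  MAE 0.0421  R2 0.8811  MedAE 0.0332
```

The 400-subject, 4-wave cohort yields 1033 supervised pairs (waves with
missing label instruments drop out). The forest explains ~69% of
held-out label variance on this synthetic world and, as expected for
deep trees, fits its training folds markedly better than its test folds.

## Command line

```sh
Rscript inst/cli/icapacity.R simulate --seed 11 --out cohort.csv
Rscript inst/cli/icapacity.R score --input cohort.csv --out scores.csv
Rscript inst/cli/icapacity.R build-dataset --input cohort.csv --domain cognition --out cog.csv
Rscript inst/cli/icapacity.R compare --input cog.csv --domain cognition --out table.csv
Rscript inst/cli/icapacity.R run --config pipeline.yaml --seed 5 --out outdir/
```

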