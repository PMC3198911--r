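# semgtorque

Estimation of isometric wrist flexion/extension torque from eight-channel
forearm surface electromyography (SEMG), for researchers benchmarking
myoelectric torque-decoding models under the conditions that break them:
reduced electrode counts, small training sets, the passage of time between
sessions, and changes of forearm posture.

The package implements, behind one fit/predict contract, six estimators of
the wrist torque τ(t) from processed SEMG envelopes e₁..e₈(t):

* a **physiological neuromusculoskeletal model**: per channel, a discrete
  recursive activation filter
  u(t) = α·e(t−d) − β₁u(t−1) − β₂u(t−2) (β₁ = C₁+C₂, β₂ = C₁C₂,
  α = 1+β₁+β₂ for unit DC gain, |C₁|,|C₂| < 1, delay d ∈ [10, 100] ms),
  exponential activation shaping a = (e^{Au} − 1)/(e^A − 1) with
  A ∈ [−3, 0], and PCSA-weighted torque summation
  τₑ = Σⱼ (ΣPCSAⱼ/PCSAⱼ)·Fmax,ⱼ·aⱼ·MAⱼ, calibrated per subject by a
  seeded genetic algorithm within physiological bounds;
* **ordinary least squares** (τ = SEMG·β, no intercept) and
  **ℓ1-regularized least squares** (lasso objective
  λΣ|βᵢ| + Σr², coordinate descent, default λ = 0.01);
* **ε-SVR** (Gaussian kernel, 8-fold CV grid search over C, γ, ε), a
  **two-hidden-layer tanh neural network** (BFGS training, early stopping,
  regularization, best of 10 restarts), and a **receptive-field locally
  weighted regressor** standing in for LWPR.

Signal conditioning follows the linear-envelope chain (DC removal,
zero-phase 4th-order Butterworth 30 Hz high-pass, full-wave rectification,
zero-phase 6 Hz low-pass, per-channel max normalization) with decimation to
every 100th sample; accuracy is reported as NRMSE (RMSE over the
volunteer's flexion+|extension| torque span), R², and adjusted R²
(Ra² = 1 − (n−1)/(n−k−1)·(1−R²), k = SEMG channels). A fully seeded
synthetic SEMG/torque cohort generator with known ground truth drives the
four benchmark experiments (channel subsets, training fraction,
cross-session, posture); see the methods vignette
(`vignettes/torque-estimation-methods.Rmd`) for the model, generator and
design details.

## Worked example

Generate one synthetic subject at the study scale (33,520 samples at
1 kHz), condition the signals, and compare two estimators on a 75/25
split:

```r
library(semgtorque)

cfg <- cohort_config()                       # study-scale defaults
sub <- synthetic_subject(cfg, seed = 5)
exc <- generate_excitation_schedule(cfg, seed = 2)
rec <- recording(synthesize_raw_semg(exc, sub, seed = 3),
                 synthesize_torque(exc, sub, noise_sd = 0.05, seed = 4))

pr  <- process_recording(rec)                # envelopes in [0,1], torque untouched
dec <- resample_every(pr, 100)
nrow(dec$envelopes)
#> [1] 335

idx <- semgtorque:::split_indices(pr, 0.75, 100)
pbm <- fit_torque_model("pbm", pr, seed = 7, idx = idx$train)
ols <- fit_torque_model("ols", pr, idx = idx$train)
ev_pbm <- evaluate_model(pbm, pr, range_from = pr, idx = idx$test)
ev_ols <- evaluate_model(ols, pr, range_from = pr, idx = idx$test)
round(c(pbm_nrmse_pct = 100 * ev_pbm$nrmse, pbm_ra2 = ev_pbm$ra2,
        ols_nrmse_pct = 100 * ev_ols$nrmse, ols_ra2 = ev_ols$ra2), 3)
#> pbm_nrmse_pct       pbm_ra2 ols_nrmse_pct       ols_ra2
#>         0.560         0.995         2.161         0.921
```

The physiological model, calibrated by the genetic algorithm within
physiological parameter bounds, tracks the held-out torque to about 0.5%
of the subject's torque span (adjusted R² ≈ 0.99); the no-intercept
linear map is respectable at about 2% but cannot capture the activation
dynamics and recruitment nonlinearity this subject was generated with. The full four-experiment study over an 11-subject cohort
is one call:

```r
study <- run_full_study(master_seed = 1, n_subjects = 11)
study$posture
condition_changes(study$posture, "baseline", "supinated", mode = "fold")
```

Cross-session and posture changes degrade every estimator (session 1 >
session 2 > session 3 in mean Ra²; supination at least doubles NRMSE),
which is the core practical finding this pipeline reproduces: myoelectric
torque models need frequent retraining, and resampling makes retraining
cheap.

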