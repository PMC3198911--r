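---
title: "Estimating isometric wrist torque from surface EMG: models, metrics and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating isometric wrist torque from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgtorque)
```

## The problem

Surface electromyography (SEMG) records the electrical activity of muscles
at the skin. For myoelectric control of wrist exoskeletons and prostheses,
a regression model must map multi-channel forearm SEMG to the isometric
torque the wrist exerts. `semgtorque` implements a complete, tested
pipeline for this problem: signal conditioning into activation envelopes,
six torque estimators behind a single fit/predict contract, the accuracy
metrics of the field, and four benchmark experiments — channel count,
training-set size, cross-session degradation, and arm-posture change —
run over a cohort. Because no public dataset pairs eight-channel forearm
SEMG with wrist torque under this protocol, the package ships a fully
seeded synthetic cohort generator with known ground truth, so every stage
is testable end to end.

Eight muscles are monitored (four extensors: ECRL, EDC, ECU, ECRB; four
flexors: FCR, PL, FDS, FCU), with torque positive in flexion and negative
in extension. Each recording follows a 14-action protocol: one
maximum-effort (MVC) flexion and extension, then three gradual ramps to
50% MVC and back per direction, then three ramps to 25% MVC per
direction; 33,520 samples at 1 kHz.

## Signal conditioning

`process_recording()` applies, per channel:

1. DC offset removal (mean subtraction);
2. zero-lag 4th-order Butterworth high-pass at 30 Hz (motion artefact);
3. full-wave rectification;
4. zero-lag 4th-order Butterworth low-pass at 6 Hz (linear envelope);
5. normalization to the channel maximum, so envelopes lie in [0, 1].

"Zero-lag" means the filter is designed once and applied forward and
backward (`zero_lag_butterworth()`): phase cancels exactly and the
effective magnitude response is the design's square. Because one-sided IIR
passes ring at the edges, each pass uses odd reflective padding together
with steady-state initial conditions; the pad is 3 × order samples,
enlarged to two cutoff periods when longer (a 6 Hz filter at 1 kHz rings
for hundreds of samples). The factor is configurable in
`processing_config()`.

Rectification must precede the 6 Hz low-pass. EMG is a 20–450 Hz
interference signal whose amplitude carries the information; low-passing
at 6 Hz before rectification would annihilate the carrier (|H| ≈ 1e-5 at
100 Hz) and no envelope would survive. The chain above is the standard
linear-envelope detector and is the only order under which the envelope
tracks a known amplitude-modulation profile, which the test suite checks.

Torque is never filtered. For recordings taken with the forearm
supinated, the torque sensor reads reversed, so its sign is flipped at
processing time (configurable), keeping flexion positive internally.

Training uses every 100th sample of the processed signals
(`resample_every()`; 33,520 → exactly 335 samples), which cuts model
training cost by orders of magnitude. A property test confirms that
resampled and full-rate training give statistically indistinguishable
accuracy (one-way ANOVA on cohort NRMSE).

## The physiological model

The physiological estimator maps each envelope $e_j(t)$ to neural
activation through a discretized critically-damped twitch model,

$$u_j(t) = \alpha\, e_j(t-d) - \beta_1 u_j(t-1) - \beta_2 u_j(t-2),$$

with $\beta_1 = C_1 + C_2$, $\beta_2 = C_1 C_2$, $|C_1|,|C_2| < 1$
(stability) and $\alpha = 1 + \beta_1 + \beta_2$, which forces exact unit
DC gain: sustained full excitation maps to full activation. The
electromechanical delay $d$ is bounded to 10–100 ms, the physiological
range for skeletal muscle, and rounded to whole samples — which is why
the recursion always runs at the full 1 kHz rate: at the decimated 10 Hz
rate the whole delay range would be sub-sample. Activation is then shaped
by

$$a_j(t) = \frac{e^{A u_j(t)} - 1}{e^{A} - 1}, \qquad A \in [-3, 0],$$

a monotone bijection of [0, 1] onto itself ($A = 0$ is handled as its
analytic limit $a = u$, never as a division by zero); filter transients
marginally outside [0, 1] are clipped before shaping. Muscle force is
$F_j = F_{\max,j}\, a_j$, torque per muscle $\tau_j = F_j \cdot MA_j$
(moment arms signed: flexors positive, extensors negative), and the wrist
torque is the PCSA-weighted sum

$$\tau_e(t) = \sum_j \frac{\Sigma PCSA_j}{PCSA_j}\, \tau_j(t),$$

where $\Sigma PCSA_j$ adds the physiological cross-sectional areas of the
deep muscles each surface channel represents (EDC→EDM/EIP/EPL, PL→FPL,
FDS→FDP). With fewer channels the unrecorded PCSA is redistributed
(`redistribute_sigma_pcsa()`): each of the two primary flexors receives
half the non-primary flexor pool, each of the three primary extensors a
third of the extensor pool, and in the two-channel case each single
muscle carries its entire role pool. The default physiological table
(`muscle_table()`) ships as an editable CSV with F~max~ means ± 1 SD,
moment arms, and PCSA values set from standard anatomy literature ranges;
PCSA values are fixed and never calibrated, since torque estimates are
insensitive to them.

### Calibration

`calibrate_pbm()` tunes $x = \{A, C_1, C_2, d, F_{\max,1..M},
MA_{1..M}\}$ (activation parameters shared across muscles — more
parameters would overfit) by minimizing the sum of squared torque
residuals at the decimated training samples, box-constrained to the
bounds above (F~max~ and MA within mean ± 1 SD, signs fixed). The
optimizer is a real-coded genetic algorithm: population 50, at most 100
generations, tournament selection, blend (BLX-α) crossover, Gaussian
mutation clipped to the bounds, elitism, fully seeded. The GA optimum is
then refined by a bounded quasi-Newton (L-BFGS-B) polish — a standard
hybrid that makes torque-level recovery reliable; it can be disabled in
`ga_config()`. The initial population always contains the mid-bounds
vector, and the returned objective never exceeds that start's objective.

On noiseless synthetic data the calibrated model recovers the generating
torque to NRMSE < 2%; with torque noise of 5% of range, < 6%. Individual
parameter values are *not* asserted to be recovered: summed torque only
weakly identifies per-muscle $F_{\max} \cdot MA$ products, so
physiological interpretation of fitted parameters should be cautious.

## Linear and machine-learning estimators

The regression models act on the decimated envelope matrix (N × M, no
intercept — the model is $\tau = \mathrm{SEMG}\,\beta + \varepsilon$):

* **OLS** (`ols_fit()`): normal equations via QR; rank-deficient designs
  error, naming the collinear columns.
* **ℓ1-regularized least squares** (`rls_fit()`): minimizes
  $\lambda \sum_i |\beta_i| + \sum_t r_t^2$ by cyclic coordinate descent
  (tolerance 1e-8, ≤ 1e5 sweeps); default $\lambda = 0.01$. The
  objective is convex, $\lambda = 0$ reproduces OLS, and the
  one-dimensional case matches the soft-thresholding closed form; an
  independent convex solver cross-checks the multivariate solution in the
  tests.
* **ε-SVR** (`fit_estimator()` with kind `"svr"`): Gaussian-kernel
  support vector regression via libsvm, with (C, γ, ε) selected by grid
  search under deterministic seeded 8-fold cross-validation. Default
  grids: C ∈ {0.1, 1, 10, 100}, γ ∈ {0.01, 0.1, 1, 10},
  ε ∈ {0.001, 0.01, 0.1}.
* **ANN** (kind `"ann"`): feed-forward network with two tanh hidden
  layers (defaults 10 and 5 units — layer sizes are a free design choice
  here), trained by BFGS quasi-Newton on a mean-squared-error loss with
  L2 regularization, early stopping on a 15% validation split (patience
  20 epochs), best of 10 seeded restarts.
* **LWPR variant** (kind `"lwpr"`): locally weighted regression with
  radial-basis receptive fields. No incremental LWPR implementation is
  available in this ecosystem, so the package provides a reduced
  receptive-field weighted-linear-model variant: kmeans-placed centers,
  each carrying a ridge-stabilized weighted linear model, blended by
  normalized RBF weights; the receptive-field distance metric is chosen
  by 8-fold CV grid search. The fitted object's metadata records the
  substitution.

All six estimators share the `fit_torque_model()` / `predict_torque()`
contract, so the experiment harness treats them uniformly, and all
stochastic fitters are exactly reproducible from their seed.

## Metrics

For estimated $\tau_e$ against measured $\tau_m$ over $n$ test samples:

* **NRMSE** — RMSE divided by $\tau_{m,flex} + |\tau_{m,ext}|$, the
  volunteer's maximum flexion plus maximum extension torque. These maxima
  are session-level constants: when a model is evaluated on a narrow
  held-out window, the harness passes the extrema of the full session
  recording, so NRMSE values are comparable across test windows of
  different composition.
* **R²** — $1 - \mathrm{SSE}/\mathrm{SST}$; negative for fits worse than
  the mean predictor.
* **Adjusted R²** — $1 - \frac{n-1}{n-k-1}(1-R^2)$ with $k$ the number of
  SEMG channels used to train the model (including for the physiological
  model). The harness uses $n$ = the number of *training* samples:
  adjusted R² is a degrees-of-freedom correction of the estimation
  sample, and using the test-window size instead would mechanically
  penalize small test windows (at $n = 34$, $k = 8$ the factor is 1.32)
  by more than any genuine effect being measured. `adjusted_r_squared()`
  itself is the pure formula; the choice of $n$ is the caller's.
* **Relative change** — percent changes are rounded half-up to integers
  and fold changes to two decimals, the granularity used in degradation
  reporting. `reported_means()` carries the original study's printed
  cohort means as *inputs* for this arithmetic; the package never claims
  to recompute those table cells, which would require the undeposited
  human recordings.
* **One-way ANOVA** (`one_way_anova()`): the classical fixed-effects F
  test, used as the omnibus comparison of models.

## The synthetic cohort

`generate_cohort()` draws subjects whose ground truth lives in the same
parameter boxes the calibration searches, then synthesizes the full
protocol per subject: a session-1 pronated and supinated recording, a
session-2 recording (one hour later) and a session-3 recording (24 hours
later, new electrodes). SEMG is modeled as amplitude-modulated
band-limited noise — the standard surrogate for interference-pattern
EMG — not a motor-unit-level simulation: each channel is its cross-talk
mixed excitation modulating a 20–450 Hz Gaussian carrier, times a channel
gain, plus DC offset, sub-5 Hz motion-artefact drift, and white
measurement noise. Torque is the ground-truth forward model on the
noiseless excitations plus 0.5%-of-range sensor noise (strain-gauge
torque sensors are precise to well under 1% of full scale).

The generator's realism choices matter for what the benchmarks can show,
so they are explicit:

* **Excitation schedule.** Agonists follow the ramp profile with
  per-muscle participation weights — 0.7–1.0 for the five primary wrist
  movers, 0.55–0.95 for EDC/PL/FDS, whose finger actions the rig largely
  suppresses (a deliberately mild deficit: the reduced-channel PCSA
  redistribution presumes the unrecorded muscles contribute roughly in
  proportion to their cross-sections) — and per-segment load-sharing jitter
  (U[0.7, 1.3]): synergists share load differently across repetitions of
  the same ramp. This jitter is the information a reduced channel set
  genuinely loses. Antagonist co-activation is 5% of the profile (15%
  supinated, an unfamiliar posture).
* **Neural-drive noise.** EMG amplitude fluctuates 10–20% around the true
  drive even at constant force (motor-unit rotation); the generator adds
  per-muscle multiplicative low-pass (2 Hz) Gaussian noise with SD 0.15
  on the EMG side only, slow enough to be physiological and fast enough
  to decorrelate between decimated samples. This sets a realistic accuracy ceiling and makes
  additional channels informative (noise averaging).
* **Within-session transient.** EMG amplitude per unit force rises
  quickly after electrode attachment and early MVC efforts
  (gel settling, potentiation/fatigue): a concave transient with time
  constant 0.15 of the session and magnitude U[0.3, 0.8], EMG side only.
* **Cross-session drift.** Session 2: per-muscle source amplitude factors
  U[0.7, 1.3] *and* per-muscle amplitude-nonlinearity exponents
  U[0.7, 1.35] on the excitation-to-EMG map. Pure gain would be cancelled
  exactly by per-channel max-normalization; the exponent changes the
  *shape* of the amplitude-force relation, which normalization cannot
  undo — that is what breaks model transfer. Session 3 draws fresh,
  wider exponents (U[0.6, 1.5]) and additionally perturbs the cross-talk
  matrix off-diagonals (up to +0.15): new electrode placement.
* **Posture change.** The supinated mixing matrix is a 50/50 blend of the
  subject's matrix with its neighbor-shifted copy (the SEMG signal space
  shifts), per-muscle moment arms are rescaled by U[0.55, 0.85] (forearm
  rotation changes leverage), co-activation triples, and the torque
  sensor reads reversed.

Drift magnitudes are set to reproduce the *qualitative* orderings of the
benchmarks — accuracy degrades hour-to-day, posture change at least
doubles error — not any particular printed degradation percentage, which
no synthetic stand-in could honestly target. All randomness flows from
explicit seeds; two cohorts from the same master seed are identical.

What the generator does *not* emulate: motor-unit action potentials,
fatigue-induced spectral compression, force–length/velocity relations
(contractions are isometric), mains interference, or feedback-control
tracking dynamics beyond ramp profiles. Passing benchmarks on this cohort
therefore demonstrates the pipeline's correctness and the direction of
the studied effects, not clinical-grade performance on human data.

## The four experiments

All experiments run per subject and report unweighted cohort means ± SD
(`summarize_cohort()`), the grain of the original study's tables.

* **Channel subsets** (`channel_subset_experiment()`): 8 channels vs the
  5 primary movers vs the best of the six flexor/extensor pairs
  (FCR/FCU × ECRL/ECRB/ECU), 75/25 split; the best pair is chosen per
  subject by held-out adjusted R² (configurable to NRMSE) and is free to
  differ across subjects.
* **Training fraction** (`training_fraction_experiment()`): 25% vs 90%
  training on all eight channels. This experiment assigns random
  contiguous *blocks* (12 decimated samples, about half an action
  segment) to the training set: a small training fraction then genuinely
  misses parts of the protocol — the mechanism by which small training
  sets hurt with sequentially collected data — while the test windows
  stay representative.

Elsewhere splits default to seeded *random* sample assignment. Under a contiguous
final-block split the held-out window is a single low-variance action
(the last 25%-MVC extension ramps): any R²-family metric computed there
measures window composition rather than model quality, and it cannot
serve as a baseline comparable to full-session cross-condition tests.
The contiguous mode (first block trains, preserving temporal precedence)
remains available via `experiment_plan(split = "contiguous")`.
* **Cross-session** (`cross_session_experiment()`): fit on session 1,
  evaluate on held-out session 1, all of session 2 and all of session 3;
  each test recording is processed (hence normalized) on its own, since
  only its own maxima are available at test time.
* **Posture** (`posture_experiment()`): fit pronated, evaluate on
  held-out pronated (baseline) and the same-session supinated recording.

Within experiments the GA budget is reduced (population 30, ≤ 25
generations, polish cap 30 iterations) and the SVR grid trimmed to
C ∈ {1, 10, 100} × γ ∈ {0.1, 1} × ε ∈ {0.01, 0.1}: a full cohort run performs
roughly 130 calibrations and grid searches per model, and these budgets
keep a six-model, 11-subject study around ten minutes on one core while
leaving the conclusions unchanged. The standalone defaults
(`ga_config()`, `estimator_config()`) keep the full budgets. The problem
sizes used throughout — 11 subjects, 33,520 samples, 335 decimated
samples — are the study scale the package simulates by default, and are
configurable in `cohort_config()`.

```{r, eval = FALSE}
study <- run_full_study(master_seed = 1, n_subjects = 11)
study$sessions          # cohort means per model and session
condition_changes(study$posture, "baseline", "supinated", mode = "fold")
```

## Numerical and degenerate-input conventions

* Identically-zero channels normalize to zeros with a warning.
* A constant measured series makes R² (and a zero torque span makes
  NRMSE) an explicit error, not NaN.
* $A = 0$ activation shaping is the analytic limit; recursion overshoot
  is clipped into [0, 1] before shaping.
* Lasso ties and convergence: coordinate descent stops when the largest
  coefficient update falls below 1e-8; grid-search ties resolve to the
  first grid entry in declaration order.
* Decimation keeps samples k, 2k, … (so 33,520 with k = 100 gives
  floor(N/k) = 335); train/test index sets never overlap.
* All cross-validation folds are seeded, deterministic, and balanced to
  within one sample.

## Known limitations

* Cohort-level conclusions mirror the qualitative behavior of human
  studies; absolute accuracy on the synthetic cohort is higher than on
  real data (no motor-unit discreteness, no spectral fatigue effects).
* The calibrated physiological parameters are identified only up to
  torque equivalence; do not over-interpret individual muscle values.
* The LWPR variant is a batch approximation of incremental LWPR;
  meta-learning of the distance metric is not implemented.
* The pipeline targets one degree of freedom (flexion/extension);
  radial/ulnar deviation and multi-DoF coupling are out of scope.
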