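---
title: "Modelling trait scores from postural sway: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trait scores from postural sway: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

swaytrait estimates a self-reported psychological trait — in the motivating
application, trait mindfulness measured by a 14-item inventory with integer
totals in 14–56 — from the center-of-pressure (CoP) trajectory recorded
during quiet standing. This vignette explains the model and the procedure,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical conventions the implementation
commits to.

## The modelling problem

A force platform samples the planar CoP position at 40 Hz for 52 s per
recording, one recording per condition (eyes closed, EC; eyes open, EO).
The postulated stochastic model is

$$y = f(\theta, \mathbf{x}) + \varepsilon,$$

where $y$ is the trait score (regression) or a binary status from a strict
median split (classification), $\mathbf{x}$ collects inputs derived from the
postural signal, and $f$ is either multilinear/logistic or a single-hidden-
layer tanh network. The pipeline has three stages: variable selection,
complexity selection, and held-out evaluation — each deliberately
conservative because cohort sizes in posturography are small (around 10^2).

## From signal to candidate variables

1. **Preprocessing.** Both axes are low-pass filtered at 10 Hz with a
   fourth-order Butterworth applied forward and backward (zero phase lag).
   Each pass uses even-reflection padding of 3 × order samples; at 2080
   samples per record the padding is negligible.
2. **Features.** Sixteen individual-specific features are extracted per
   recording: the mean sway-density peak at R = 3 mm and the slope of the
   mean peak against R ∈ {2,…,5} mm; mean ML/AP positions; the
   zero-crossing count of the filtered AP velocity; Gamma shape and scale
   fitted to supra-threshold speed-run durations per axis; log path length;
   log mean velocities (planar, ML, AP); log spectral powers (planar, ML);
   and the 95% power frequency of the AP spectrum.
3. **Normalisation.** Features are z-scored. The default reference is the
   whole sample, matching the original analysis; a training-only option is
   available (and recommended for new studies) to avoid test-set leakage.
4. **Cross-terms.** All 120 unordered pairwise products of the 16
   normalized primaries are appended and re-z-scored, giving 136 candidates
   on a common scale. Products of normalized features are used so a
   cross-term carries interaction information rather than the shared scale
   of its factors; the re-z-scoring keeps the cosine ranking comparable
   across primaries and products.

## Variable selection: OFR with random probes

Candidates live in observation space (one coordinate per subject).
Orthogonal forward regression iteratively selects the candidate with the
largest squared cosine to the current response, then deflates the remaining
candidates and the response by its component along the selection (modified
Gram–Schmidt). Vectors are centered first, making the squared cosine equal
the squared Pearson correlation; because candidates are already z-scored
the two formulations coincide, and centering makes the Gaussian probes
exchangeable with the candidates under the null.

One hundred i.i.d. standard-normal probe vectors are ranked jointly with
the candidates. A candidate's *probe risk* is the fraction of probes ranked
before it — the estimated probability that pure noise outranks it. The
retained set is the maximal prefix of the candidate ranking whose members
all have risk at or below the threshold. The prefix rule (rather than
per-variable filtering) is deliberate: OFR relevance is conditional on all
earlier selections, so keeping a later variable while discarding an earlier
one would condition on a selection believed spurious. A per-variable mode
exists behind a flag; null-calibration checks use it because the marginal
risk distribution is what the probe construction calibrates.

Thresholds are task and condition inputs, not derived quantities: 0.10 for
EC (both tasks), 0.05 for EO regression, 0.20 for EO classification.

## Complexity selection: Jacobian screening and leave-one-out

Model families are indexed by the number of hidden units h ∈ {0,…,5}
(h = 0 is the multilinear or logistic model). Two mechanisms control
complexity:

* **Jacobian rank screening.** For a trained model the N × q matrix of
  output derivatives with respect to each of the q parameters is computed
  analytically. Rank deficiency (singular values below
  max(N, q)·eps·σ_max) means some parameters act linearly dependently —
  the family is overparameterised for the data and is discarded before
  scoring. For classifiers the derivative is taken on the pre-logistic
  output so deficiency reflects parameter redundancy, not sigmoid
  saturation.
* **Leave-one-out.** One LOO run draws a single initial parameter vector
  and performs N refits, each excluding one example and starting from that
  same initialisation. The regression score is the mean squared
  withheld-example error (reported as its square root, sharing the RMSE
  unit in complexity plots; the raw mean is stored too); the
  classification score is the withheld misclassification fraction at
  probability threshold 0.5. Per complexity, `n_restarts` LOO runs with
  distinct initialisations are performed and the smallest score kept; the
  selected complexity minimises that score. For reproduction-fidelity runs
  `n_restarts = 300`; the package's test fidelity uses 4–20. A warm-start
  variant (refits start from the full-data fit) exists for exploration and
  is not used in reproduction runs.

Training minimises the sum of squared residuals by Levenberg–Marquardt
with the analytic Jacobian (regression) or the cross-entropy by BFGS with
the analytic gradient (classification); h = 0 uses the exact QR and IRLS
fits. Initial parameters are N(0, 0.1²), seeded; optimiser budgets are 500
iterations with gradient tolerance 1e-8. The tanh hidden layer with biases
on hidden and output units is the standard architecture of this
methodology; the activation and classification loss are design choices
here (squared-error classification is available behind the training seam
for fidelity experiments).

## Evaluation

Subjects are split 70/30 into training/validation and test (156 subjects
give 109/47), stratified on the median-split status and seeded; the
original study does not state its randomisation, so stratification is this
package's choice to keep class shares comparable across subsets. Test-set
metrics are RMSE and Pearson correlation (regression) or accuracy,
sensitivity, specificity and the rank-statistic AUC (classification),
always next to a baseline: the training/validation-mean predictor, whose
correlation is reported as 0 by the degenerate-predictor convention, or
the fair-coin classifier with 50% expected accuracy and AUC 0.5. Selection
and complexity choice see only training/validation rows.

## The synthetic cohort generator

Access to the motivating study's recordings is restricted, so the package
ships a generator that emulates the statistical structure the analysis
assumes:

* **Sway process.** Each axis of each subject follows a noise-driven damped
  oscillator $\ddot{x} = -2\zeta\omega\dot{x} - \omega^2(x - \mu) + \sigma\xi(t)$,
  discretised by Euler–Maruyama at the sampling rate with a 1 s burn-in.
  This is the simplest process that concentrates sway power below 2 Hz and
  has a stationary amplitude $\sigma^2/(4\zeta\omega^3)$, matching the
  low-frequency character of quiet-standing CoP.
* **Random effects.** Natural frequency (0.4 ± 0.08 Hz), damping ratio
  (0.7 ± 0.1), noise intensity (15 ± 3 mm·s^-3/2) and per-axis offsets
  (0 ± 3 mm) vary between subjects, creating the between-subject feature
  variance that z-scoring and selection require. Draws are truncated
  (frequency to [0.15, 0.8] Hz, damping to [0.3, 1.2], noise to at least a
  third of its centre) so no simulated subject is quasi-static — real
  cohorts of healthy adults contain none. Eyes-closed recordings receive a
  1.3× noise gain, the usual direction of the Romberg effect.
* **Planted response.** The trait-like response is
  `intercept + Σ effect_j · z(t1_j)z(t2_j) + ε` with the z-scores taken
  over the cohort's realized EC features. Planting on cross-terms rather
  than primaries mirrors the selection outcome the method was designed to
  detect and makes recovery tests meaningful. Defaults: intercept 41 and
  noise SD 4, giving integer totals with mean ≈ 41 and SD ≈ 6 after the
  round-and-clip link (the published cohort's scale); effects (4, 3) on
  (Mean-ML × log-Alpha-AP, Mean-ML × PF95AP), the pairs the original EC
  analysis retained. A latent-continuous link provides tie-free scores for
  exact median-split balance.

What the generator does **not** emulate: non-stationarity and fatigue
drift within a trial, the weight/height dependence of sway, heteroscedastic
measurement noise of real platforms, and any dependence of the response on
features beyond the planted terms. Passing recovery tests therefore shows
the chain detects the structure it targets under realistic signal-to-noise,
not that the published real-data effect sizes are reproduced — those rest
on restricted-access recordings.

## Numerical conventions and degenerate inputs

* Sway density counts consecutive samples (both directions, self included)
  within R of the current point; the curve is smoothed with a 0.5 s moving
  average (partial windows at the edges) before peak picking. Peaks are
  plateau-aware local maxima (a run of equal values strictly above both
  flanks counts once, at its midpoint) at least 0.25 s apart; a fully
  saturated, constant curve counts as a single stabilisation episode whose
  peak value is the record duration.
* Velocity is the central finite difference; speed-run durations above the
  record-mean speed are the Gamma-modelled quantity (bursts between
  mean-velocity crossings, the convention of the individual-specific
  feature literature). The Gamma MLE uses Newton steps on the shape from a
  method-of-moments start; numerically equal durations cap the shape at
  1e8, preserving the mean αβ.
* Welch spectra use 10 s Hann segments with 50% overlap on the
  mean-removed series; powers integrate the one-sided PSD over
  (0, Nyquist].
* Log-features with non-positive arguments (zero path length of a constant
  trace, for example) raise a "degenerate recording" error rather than
  emitting −Inf: such inputs are physically impossible and indicate
  ingestion bugs.
* OFR ties break to the lowest column index; ranking stops when the
  residual response norm falls below 1e-10 of its initial value; once the
  observation-space dimension is exhausted the remaining candidates are
  unrankable by construction and appended without a warning (an *early*
  zero-norm collapse, i.e. a duplicated candidate, still warns).
* The CoP of four-sensor frames is the load-weighted barycenter by default
  (a pressure centroid is physically load-weighted; equal loads recover
  the plain average, which is also available) — the device documentation
  speaks only of "averaging", so both conventions are provided.
* Median-split ties go to the non-mindful class; exact class balance holds
  only for tie-free scores.

## Problem sizes used by the test and acceptance suites

Chosen once, as a compromise between statistical resolution and a
single-CPU run: selection-recovery uses 50 seeds of n = 200 Gaussian
feature tables with effects (4, 3) and response noise SD 4; probe-null
calibration uses 30 replicates at n = 100; end-to-end planted cohorts use
20 seeds of 100 subjects (EC, regression, complexities 0–2, 4 LOO restarts)
and effectless cohorts 20 seeds of 60 subjects (EO, classification). The
full-fidelity configuration (156 subjects, complexities 0–5, 300 restarts)
is expressed by the same functions with `fidelity = "paper"`.

## Known limitations

* The supplementary definitions of the original feature computations were
  not available; the conventions above follow the individual-specific
  feature literature and are centralised in `feature_config()` so they can
  be revised in one place.
* LOO with refits is O(N) trainings per run; at full fidelity the sweep is
  computationally heavy by design (that is the method), and the warm-start
  mode is the only concession offered.
* The AUC uses the rank statistic; confidence intervals and ROC-comparison
  tests are out of scope.
* With integer trait scores, ties at the median make exact 50/50 class
  balance unattainable; the latent link exists precisely for tests that
  need tie-free scores.
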