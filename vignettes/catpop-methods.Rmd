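---
title: "Recurrent population codes for categorical perception: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent population codes for categorical perception: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catpop)
```

## The inference problem

`catpop` models categorical colour perception as *online statistical
inference*.  The environment is a hierarchical hidden Markov model on the
hue circle: a discrete colour category $c_t$ evolves slowly (per-step
switch probability $\rho$, uniform over the other categories), the hue
$s_t$ is drawn each step from the category's von Mises emission
$p(s\mid c) \propto \exp\{\kappa_{\mathrm{cat}}\cos(s-\mu_c)\}$, and the
sensory observation $o_t$ is the hue corrupted by wrapped-Gaussian noise
(SD 10 azimuth degrees by default, matching reported human hue
discrimination).  The Bayes-optimal observer filters
$p(s_t \mid o_{1:t})$ by marginalising over category paths;
`exact_online_posterior()` implements this filter exactly on a hue grid
and serves as the oracle throughout the test suite, where it is itself
verified against brute-force enumeration of category paths on tiny
instances.

## The recurrent network

The approximate, neurally plausible implementation is a probabilistic
population code with two interacting populations:

* $N$ *hue-selective units* (default 300) with evenly spaced preferred
  hues $\theta_i$ and peak-normalised von Mises tuning
  $f_i(s) = g\,e^{\kappa(\cos(s-\theta_i)-1)}$.  With $\kappa = 2$ the
  half-width at half maximum is about $49^\circ$, in the range reported
  for IT colour cells; $g$ is the peak rate, so gain statements read
  directly off the tuning.
* $n$ *category-selective units* (default 3, centres equally spaced).
  Their drive is a linear readout of the hue population,
  $u_c = \sum_i \kappa_{\mathrm{cat}}\cos(\theta_i-\mu_c)\, r_i$ — the
  log of the category-conditional von Mises without its normaliser,
  which cancels in the argmax.  A winner-take-all competition keeps only
  the maximally driven unit (ties to the lowest index, documented and
  deterministic).

One time step of `update_step()` applies the three-term recurrence

$$ r_i(t) \;=\; b_i(t) \;+\; \lambda_{\mathrm{hue}}\, r_i(t-1) \;+\;
   \lambda_{\mathrm{cat}}\, h\!\big(\theta_i - \mu_{\hat c(t-1)}\big), $$

where $b_i(t)$ is the bottom-up input (the tuning curve evaluated at the
noise-perturbed stimulus), the lateral self-feedback term implements the
*continuity prior*, and the bell-shaped top-down profile
$h(d) = e^{\kappa_{\mathrm{td}}(\cos d - 1)}$ implements the
*categorical prior* around the focal hue of the category estimated at
the previous step.  Activities are rectified at zero by default
(rectification never binds in the default regime).  While the activity
is identically zero there is no evidence, hence no category estimate and
no top-down term; this makes an all-blank trial stay silent and avoids a
spurious tie-break bias toward the first category on the first stimulus
step.

Decoding uses either the argmax unit's preferred hue (`decode_peak()`,
grid resolution $2\pi/N$) or the activity-weighted circular mean
(`decode_population_vector()`), which is exact on symmetric profiles and
is used wherever sub-grid resolution matters (e.g. clustering).

### Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| $N$ | hue units | 300 | simulated network scale |
| $\kappa$ | tuning sharpness | 2.0 | HWHM $\approx 49^\circ$, plausible for IT |
| $g$ | peak rate | 1.0 | rate unit |
| $n$ | categories | 3 | equally spaced focal hues |
| $\kappa_{\mathrm{cat}}$ | emission concentration | 4.0 | circular SD $\approx 29^\circ$: three $120^\circ$ categories separate cleanly with modest overlap |
| $\kappa_{\mathrm{td}}$ | top-down sharpness | $\kappa_{\mathrm{cat}}$ | the signal encodes that prior |
| $\lambda_{\mathrm{hue}}$ | continuity weight | 0.7 | phenomena robust over $[0.5, 0.9]$ |
| $\lambda_{\mathrm{cat}}$ | categorical weight | $0.3\,g$ (categorization), $0$ (discrimination) | task context |
| noise SD | sensory noise | $10^\circ$ | human hue-discrimination scale |
| $\rho$ | switch probability | 0.02 | slow category dynamics |

$\lambda_{\mathrm{hue}}$ and $\lambda_{\mathrm{cat}}$ are effectively
the only tunable parameters; a single shared configuration
(`default_model()`) drives every phenomenon below — there is no
per-phenomenon retuning.

### Approximation quality, honestly stated

The recurrence is an approximation, and its fidelity to the exact filter
is *measured*, not assumed: `scripts/acceptance.R` computes the mean
per-step correlation between the log-domain activity profile and the
exact log-posterior on slowly switching sequences.  Two structural gaps
keep that correlation below perfect agreement.  First, the generative
hue is redrawn every step, so the exact posterior is dominated by the
current observation (likelihood concentration $\approx 1/\sigma^2
\approx 33$ versus prior concentration 4), while the network's
continuity term retains a substantial stale-observation component at
$\lambda_{\mathrm{hue}} = 0.7$.  Second, the network's bump width is set
by $\kappa$, not by the posterior's width.  The correlation is
insensitive to the second gap (log-domain shapes are affine in
$\cos$-distance) but pays for the first after large hue jumps.  We keep
the documented defaults rather than sharpening the emission or shrinking
$\lambda_{\mathrm{hue}}$ to flatter the oracle comparison.

## Ideal-observer analysis

For Poisson-like statistics the Fisher information of the (effective)
population code is $J(s) = \sum_i f_i'(s)^2 / f_i(s)$ and the asymptotic
discrimination threshold is $\delta(s) \propto 1/\sqrt{J(s)}$ (the
constant is absorbed by normalisation; all reported profiles are
normalised).  `effective_tuning_at_step()` measures the tuning actually
realised by the recurrent network at a given post-onset step by
trial-averaging over sensory-noise draws; step 2 probes the early and
step 20 the late (near steady-state) response.

Numerical choices that matter here:

* **Derivatives.**  $f_i'$ is computed by the 4th-order centred
  five-point stencil on the circular stimulus grid.  The second-order
  stencil's $O(h^2)$ truncation error ($\sim 10^{-6}$ at 3600 grid
  points) would be of the same order as the closed-form tolerance the
  test suite demands; the 4th-order stencil leaves $\sim 10^{-11}$.
* **Common random numbers.**  One matrix of per-step, per-trial noise
  offsets is drawn once and shared by all grid stimuli.  The Fisher
  statistic differentiates a Monte-Carlo estimate; with independent
  draws per stimulus the finite-difference step amplifies trial noise by
  $O(1/h)$ and swamps $J$ with jitter (tens of percent at 200 trials).
  With common draws the trial-averaged tuning is an *exact* function of
  circular distance whenever the top-down term is off, so any remaining
  stimulus dependence is categorical signal, not sampling noise.
* **Zero rates.**  Terms with $f_i = f_i' = 0$ contribute zero; a zero
  rate with nonzero slope is singular and raises an error rather than
  silently producing infinite information.

## The four phenomena

All four drivers consume the one shared `default_model()`:

1. **Gain modulation** (`run_gain_modulation()`): comparing
   categorization ($\lambda_{\mathrm{cat}} > 0$) with discrimination
   ($\lambda_{\mathrm{cat}} = 0$), response amplitudes rise while
   per-unit tuning-curve correlations stay near 1 and preferred hues do
   not shift systematically — the positive feedback loop acts as an
   approximately linear amplifier.
2. **Clustering** (`run_clustering()`): decoded (population-vector hue,
   peak height) points for evenly spaced stimuli move toward the focal
   colours, shrinking the within/between-category distance ratio
   relative to the raw stimuli.  The population-vector decoder is used
   here because peak decoding would quantise away biases smaller than
   one grid spacing.
3. **Memory drift** (`run_memory()`): after one (noiseless by default)
   encoding step the bottom-up input is set to zero and the units
   receive only lateral and top-down signals; the decoded peak drifts
   monotonically to the nearest category centre, which is an exact fixed
   point.  A stimulus exactly on a category boundary drifts in the
   direction fixed by the documented lowest-index tie-break.
4. **Discrimination threshold** (`run_discrimination()`): the late
   (step 20) threshold profile, normalised by the early (step 2) one, is
   higher at category centres than at boundaries — within-category pairs
   are harder to discriminate.  In this implementation the early profile
   is *not* flat: one top-down application has already occurred by step
   2 (weight $0.3$ against an accumulated bottom-up drive of $1.7$), and
   the trial-averaged winner-take-all flip concentrates steep activity
   derivatives at the boundaries, producing narrow threshold dips there
   (about $0.7\times$ the profile mean) even this early.  Every constant
   involved is a documented default, so we report the early flatness
   ratio as measured rather than engineering it away; the late/early
   *normalised* comparison, which is how the profile is reported, shows
   the categorical structure cleanly.

## The recording-analysis pipeline

`neuroanalysis` reproduces a population-level peak-shift analysis for
multi-task recordings (fixation, categorization, discrimination; 11
sample stimuli on a red-to-green line; 50-ms bins spanning 100–550 ms):

1. classify each neuron's preferred stimulus by the argmax of its
   stimulus-mean response in the *fixation* task (the task-neutral
   condition, which also anchors normalisation; a config option allows
   all-task means);
2. divide every rate by the neuron's maximum fixation response;
3. for each (task, stimulus, bin), average the normalised rates within
   preferred-stimulus groups into an 11-point population profile;
4. fit $A e^{-(x-\mu)^2/(2\sigma^2)}$ by least squares over the *linear*
   index 1..11 (the stimuli span a line, not a circle), multi-start at
   the argmax and the rate-weighted mean, no baseline term by default;
   fits with $\mu$ outside $[1, 11]$ are flagged unreliable — the
   boundary effect that motivates excluding stimuli 1 and 11 downstream;
5. difference the fitted peak loci between tasks per stimulus 2..10 and
   bin, normalising each stimulus's curve by its absolute difference at
   the 100-ms bin (a floor of $10^{-3}$ index units guards the division;
   floored stimuli are reported unnormalised and flagged);
6. bootstrap over neurons (100 resamples, preference assignment reused
   rather than re-classified, so error bars reflect neuron sampling, not
   classification noise) and locate the category boundary as the
   interpolated sign change of the late-window (450–550 ms) mean shifts.

Because the recordings this pipeline was designed for are not public,
`generate_synthetic_recording()` provides a ground-truth stand-in: 125
neurons balanced over 11 preferred stimuli, Gaussian tuning over the
stimulus index (SD 1.8), task gains (categorization $1.2\times$), and a
time-growing displacement $\Delta(t) = \Delta_{\max}\, t/550$ of the
effective stimulus away from a configurable boundary (default between
stimuli 5 and 6), applied in the categorization task.  The fixation task
is kept neutral by default precisely because it anchors classification
and normalisation; a fixation shift is available via `shift_tasks`.
Additive rate noise (SD 0.1) is rectified at zero.

What the generator does *not* emulate: Poisson spiking and its
rate-dependent variance, trial-to-trial noise correlations, response
latencies and temporal envelopes, non-Gaussian tuning asymmetries, and
unbalanced preferred-stimulus distributions.  Pipeline tests passing on
this generator therefore demonstrate correctness of the analysis code
and its statistical calibration under known ground truth — not that the
analysis is robust to every property of real spike data.

## Reproducibility and problem sizes

All randomness flows through R's global RNG; the CLI (`exec/catpop`) and
`scripts/acceptance.R` derive per-section seeds from a single `--seed`.
Simulation sizes used by the shipped analyses — 72-stimulus grids with
200 noise draws for threshold profiles, 100 draws for tuning
measurements, 10 seeds for the clustering contrast, 100 bootstrap
resamples — were chosen so the full analysis reruns in about a minute
while keeping Monte-Carlo error well below the effects being measured;
all are arguments, not constants.

## Known limitations

* The hue space is one-dimensional; cone-opponent front ends and 2D/3D
  colour spaces are out of scope.
* The category chain is the minimal slow chain (single switch
  probability, uniform off-diagonal).
* The mapping from model time steps to milliseconds is a free scaling;
  the package reports steps.
* Non-uniform (human-calibrated) category centres are supported through
  configuration but are not a modelled default.
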