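---
title: "Models and methods behind mtobjmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtobjmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtobjmotion)
```

# The scientific problem

A moving observer sees almost everything move on the retina, so detecting an
object that moves *relative to the scene* cannot be done from image motion
alone. One solution available to a binocular observer is to compare the two
depth estimates each object affords: depth from binocular disparity
(`d_BD`) and depth from motion parallax (`d_MP`, the image motion produced by
the observer's own translation). For a world-stationary object the two agree;
for an object that moves in the world they conflict, and the conflict
`ΔDepth = d_MP − d_BD` is a direct cue that the object is "dynamic".
Neurons in macaque area MT are tuned to depth from both cues, and a
subpopulation has *mismatched* ("opposite") depth-sign preferences for the two
cues. Such neurons respond selectively to cue-conflict stimuli, making them a
plausible neural substrate for object-motion detection during self-motion.

`mtobjmotion` implements the complete analysis chain for this question:

1. **Stimulus geometry** — the cue-conflict design and its ray-trace.
2. **Synthetic population** — an MT-like generator so every stage is testable
   without recorded data.
3. **Tuning metrics** — depth-sign indices, permutation tests, congruency.
4. **Detection metrics** — ROC ideal observer (neurometric performance, NP),
   choice-sorted detection probability (DP), choice-related time courses.
5. **Behavior** — psychometric curves, per-location logistic choice
   regression.
6. **Decoding** — correlated-noise pseudo-population simulation, linear
   discriminant readout, predicted DP, subgroup decoding.

The numbered scripts under `analysis/` run these stages in order over one
canonical synthetic dataset and write their tables under `results/`.

# Stimulus geometry

The observer is translated laterally along a modified sinusoid: a 0.5 Hz
sine multiplied by a flat-topped Gaussian envelope

$$G(t) = \exp\!\left(-\frac{(t - t_0)^n}{\sigma^n}\right),
\qquad t_0 = 1.0\ \mathrm{s},\ \sigma = 0.92,\ n = 22,$$

which is essentially 1 through the middle of the 2.1-s trial and rolls the
motion on and off smoothly at the ends. Amplitude is up to 2.8 cm; the
platform updates at 60 Hz. `motion_envelope()` and `platform_trajectory()`
implement this with the velocity obtained analytically (a quadrature test
confirms consistency).

The depth conflict is applied symmetrically about a fixed **pedestal depth**
of −0.45 deg of equivalent disparity:

$$d_{MP} = \mathrm{pedestal} + \Delta/2, \qquad
  d_{BD} = \mathrm{pedestal} - \Delta/2 .$$

This half-split convention is forced by the printed extremes of the dynamic
object's depth range (−1.215 to +0.315 deg at Δ = ±1.53 about −0.45). The
standard design crosses seven conflict values
(±1.53, ±0.57, ±0.21, 0) with nine stationary depths (−1.6 to +1.6 deg in
0.4-deg steps), for 16 unique in-RF conditions. The design's verbal
description of the stationary grid ("seven depths") disagrees with its stated
endpoints and step, which give nine; we adopt nine because only 7 + 9
reproduces the stated 16 conditions.

`raytrace_dynamic_object()` renders the conflict: the image trace of a
world-fixed point at `d_MP` is re-projected frame by frame onto the depth
plane defined by `d_BD`, where the object is drawn. Monocularly the dynamic
object is therefore indistinguishable from a stationary object at `d_MP`
(asserted to 1e−9 in the tests); binocularly its disparity says `d_BD`. Depth
(deg of equivalent disparity) and viewing distance convert through the
small-angle relation $\delta = I(1/D - 1/Z)$ with interocular distance
`I = 3.0` cm (macaque) and `D = 30` cm; negative values are near. Only
relative geometry matters for any tested property.

# The synthetic MT population

Each neuron has a baseline rate and one Gaussian depth-tuning bump per cue:

$$r_{cue}(d) = \mathrm{baseline} +
  \mathrm{gain}_{cue}\exp\!\left(-\frac{(d - \mathrm{pref}_{cue})^2}
  {2\,\mathrm{width}_{cue}^2}\right).$$

Defaults (units deg and spikes/s): baseline U(5, 15); widths U(0.6, 1.4);
disparity gains U(20, 60) but parallax gains only U(5, 25), because MT
responses to depth from motion parallax are substantially weaker than to
disparity (parallax is carried by slow retinal speeds); parallax preferred
depths U(0.6, 1.8) in magnitude with a 75% near bias, disparity preferred
depths U(0.1, 1.0) in magnitude. The asymmetric preferred-depth magnitudes
follow the experimental logic that the −0.45-deg pedestal was chosen as the
average midpoint between typical parallax and disparity preferences — deep
near parallax preferences paired with moderate disparity preferences put that
midpoint near −0.45. Half the cells are *opposite* (disparity sign flipped
relative to parallax), matching the roughly even congruent/opposite split in
MT.

The detection-task response is a rectified additive combination of the two
bumps evaluated at the cue-specific depths,

$$\mu(d_{BD}, d_{MP}) = \max\{0,\ \mathrm{baseline} +
  w_{BD}\,b_{BD}(d_{BD}) + w_{MP}\,b_{MP}(d_{MP})\},$$

with both weights 1 by default. For a stationary object
(`d_BD = d_MP`) this is the congruent sum of the two cues at the object's
depth; an opposite cell reaches its global maximum only when the two cues
disagree in its preferred directions — the mechanism under study. Trial noise
is Gaussian with SD $k\sqrt{\mu}$ truncated at zero, `k = 1` (a dispersion
stand-in for spiking variability; all downstream metrics use rate means and
SDs only).

Choices come from a minimal shared-latent decision model. Per trial,

$$u = s\,\cdot\,\mathrm{sensitivity}\cdot|\Delta| \;+\;
      c_{choice}\, z \;+\; \varepsilon,$$

with `s = +1` if the dynamic object is in the receptive field and −1
otherwise, `z, ε ~ N(0,1)`, lapse 0.02, and the same latent `z` added to every
neuron's rate as $c_{neural}\, s_i \sqrt{\mu}\, z$, where `s_i` is the
neuron's dynamic-preference sign. Defaults `sensitivity = 2.6` deg⁻¹,
`c_choice = 1.0`, `c_neural = 0.5` give a psychometric curve at chance for
Δ = 0, ~65% at |Δ| = 0.21 and near-perfect at |Δ| = 1.53, and give
dynamic-preferring neurons detection probabilities above 0.5 — the structure
the analyses are designed to measure. A `monocular` flag removes the stimulus
term entirely (no disparity, no usable conflict), forcing chance performance.
At Δ = 0 both objects are identical stationary-pedestal stimuli and the
"correct" side is an arbitrary label, so chance there is guaranteed by
construction.

Each conflict level is repeated 35 times per session (the study's mean
repetition count); the dynamic object lands in the receptive field with
probability 0.5, and the companion stationary depth is drawn uniformly from
the nine-depth grid.

## What the generator does and does not emulate

It emulates: the 16-condition design and repetition counts; a
congruent/opposite mixture with near-biased, weak parallax tuning; rate
noise scaling with the mean; choices coupled to stimulus and to shared
neural noise; monocular collapse. Passing tests on these data therefore
show that the *analysis chain* recovers structure a population of this kind
generates — not that real MT data contain that structure.

Known divergences from the recorded data:

* **All neurons share one session.** The study recorded one neuron per
  session, so session-specific choice noise averaged out across its
  population. Here the 35 ambiguous trials are common to all neurons, and
  occasional seeds produce population-wide attenuation of the DP–NP
  correlation. The canonical seeds used by the workflow show the typical
  behavior.
* **A linear readout can exploit design micro-structure.** The pedestal
  (−0.45 deg) is not on the stationary grid, and smooth Gaussian tuning
  gives a pseudo-population measurable information about that tiny depth
  offset; decoder accuracy is therefore *not* monotone in |Δ| here, unlike
  in the recorded data where near-zero conflicts are genuinely hard.
* **Predicted DP in the least selective tercile stays above 0.5.** With the
  near bias, even low peak-ratio cells keep NP > 0.5 (the same bias that
  makes the mean NP exceed 0.5), and the NP-structured noise model then
  correlates every neuron positively with the decoder output. In the
  recorded data the lowest tercile included more anti-selective cells and
  its median predicted DP sat at 0.5. The corresponding acceptance check is
  intentionally left failing rather than papered over.

# Tuning metrics

The **depth-sign discrimination index** (DSDI) averages, over the four
symmetric depth-magnitude pairs of the nine-point grid, the signed difference
between far and near mean responses normalized by that difference plus the
average of the two per-depth SDs:

$$\mathrm{DSDI} = \frac{1}{4}\sum_{i=1}^{4}
  \frac{R_{far}(i) - R_{near}(i)}{|R_{far}(i) - R_{near}(i)| +
  \sigma_{avg}(i)} \in (-1, 1),$$

negative = near-preferring. The analogous conflict-sign index uses the three
symmetric nonzero conflict pairs of dynamic-object responses. A pair with
zero difference *and* zero dispersion is an indeterminate 0/0 limit; it
contributes 0 ("no evidence"). The index is invariant to adding a constant
to all responses and negates under depth-axis reversal (both are tested).

Significance uses a permutation test that shuffles trial rates jointly
across depth labels (preserving per-depth counts, 1000 shuffles) and takes a
*sign-selected one-sided* p: the fraction of shuffled indices below the
measured value when it is negative, above when positive. Implemented
literally, this rule rejects a true null at about twice the nominal level
(each tail at α); the suite measures this and the calibration check for this
test documents the inflation rather than silently redefining the test. The
detection-probability permutation test, by contrast, uses a doubled
two-sided p (`2·min(tails)`, clipped to `[1/n_perm, 1]`) and calibrates at
the nominal level.

**Congruency** is the Pearson correlation `R_MP_BD` between the two cues'
nine depth means; cells are classified congruent/opposite when it differs
from zero at α = 0.05, otherwise unclassified. The **peak response ratio**
is the largest per-condition mean over dynamic conditions divided by the
largest over stationary conditions. Across-neuron structure is summarized
with Spearman correlations (robust to the ratio's skew).

# Detection metrics

`roc_area()` is the rank-sum (Mann–Whitney) area: the probability that a
draw from the preferred group exceeds one from the other, ties counted ½.
It is checked exhaustively against pair counting for all group sizes ≤ 8.

**Neurometric performance** compares, at each nonzero conflict level, the
dynamic-in-RF trials against *all* stationary-in-RF trials pooled over
depths, and averages the six areas. **Detection probability** uses only the
ambiguous (Δ = 0) trials: rates are z-scored pooling both self-motion phases
(the design balances phase, so pooling is unbiased), sorted by the animal's
choice, and the area computed with chose-in-RF preferred. A neuron is
eligible only with at least five choices on each side. The two metrics are
computed from disjoint trial sets by construction (Δ = 0 versus Δ ≠ 0).

The **choice-sorted time course** compiles ambiguous-trial rasters into
per-trial rate traces, smooths with a 150-ms boxcar, z-scores with a
session-wide mean and SD, sorts by phase then choice, and tests the two
choice groups at every time point at α = 0.05. Because the two choice groups
are independent trials of generally unequal counts, a paired signed-rank
statistic is not computable; the per-time-point test is the two-sided
Wilcoxon rank-sum. Phase-by-choice cells with fewer than two trials are
omitted and flagged.

# Behavior

`psychometric()` reports percent correct per signed conflict level with
exact (Clopper–Pearson) binomial 95% intervals. The choice regression fits,
for each candidate location *i*, a maximum-likelihood binary logistic model
of "location *i* chosen" on the 3·N predictors |d_BD|, |d_MP|, |ΔDepth| of
every location, then averages coefficients over chosen-location terms and
over not-chosen terms, and reports the fraction of per-location coefficients
significant at α = 0.05 with the divisor equal to the total number of
coefficients of that kind. With two locations the two fits are exact mirror
images; both are fit and averaged anyway for fidelity to the procedure.
"Normalized" coefficients z-score each predictor before fitting so the betas
are per-SD effects; raw-scale fits are always reported alongside. No penalty
is applied; fits that fail to converge or show separation are flagged and
excluded from the averages.

Because |d_BD| and |d_MP| are identical on stationary locations and highly
correlated on dynamic ones, their individual weights are weakly identified
in any single session; the dominant conflict weight is recovered
per-session, and the finer ordering only on session-averaged estimates. A
200-session interval-coverage study against a generator with known weights
(run by the acceptance suite) verifies the fitting machinery at nominal
coverage.

# Decoding

Per-neuron condition moments (mean and SD of the rate in each of the 16
in-RF conditions; neurons must have at least two trials in every condition)
define a pseudo-population. Simulated trials draw a condition uniformly with
replacement and set

$$\mathbf{r} = \boldsymbol\mu(c) + Q\,\mathbf{z} \circ \boldsymbol\sigma(c),
\qquad \mathbf{z} \sim N(0, I),$$

with `Q` the symmetric (principal) square root of the noise-correlation
matrix, or the identity for independent noise. Rates are deliberately not
truncated — the construction is taken literally so that the empirical
means, SDs, and pairwise correlations converge exactly to their targets
(checked at 100,000 samples: means within 3σ/√n, correlations within
±0.03). The correlation model ties noise to tuning similarity:

$$r_{ij} = 1.1\,(0.5 - |NP_i - NP_j|),$$

unit diagonal. The implementation carries an eigenvalue-clipping repair for
non-PSD inputs, but the model matrix is provably PSD for any NP values in
[0, 1] (the absolute-difference kernel is conditionally negative definite;
the smallest eigenvalue is exactly 0.45), so the repair never fires in
practice — the tests assert this stronger property.

The readout is a two-class linear discriminant with pooled covariance
(pseudo-inverse when singular) and empirical-prior threshold, trained on 90%
of trials with ambiguous trials excluded from training, evaluated on the
held-out 10%. Ties at the boundary are broken by a seeded coin flip.
Predicted detection probability (`DP_pred`) recomputes DP with the decoder's
choice standing in for the animal's, on ambiguous test trials only, and is
aggregated over repeated simulations with percentile CIs. Subgroup decoding
splits the population into terciles by a grouping statistic (sizes ⌈n/3⌉
then equal — 33/32/32 at n = 97), decodes each with its own NP-structured
noise, and adds a size-matched "mixed" subgroup redrawn every simulation;
mixed-subgroup `DP_pred` is averaged per neuron over the subsamplings that
included it.

# Problem sizes and numerical choices

The workflow and tests use sizes chosen to keep Monte-Carlo error well below
the effects of interest: 100-neuron populations; 35 repetitions per conflict
level; 1000 permutations per test; 100,000 samples for the moment-convergence
check and headline decode; 20,000-sample, 3-simulation cycles for the
correlated-versus-independent comparison (20 paired runs); 6000-sample
simulations × 500 per tercile for subgroup decoding; 200 simulated sessions
of 400 trials for regression coverage; calibration over 1000–2000 null
neurons. All stochastic entry points take explicit integer seeds; the
pipeline derives stage seeds from one master seed and records them in a run
manifest, and two runs with the same configuration and seed produce
byte-identical outputs.

Numerical conventions collected in one place: ROC ties count ½; DSDI 0/0
pairs contribute 0; the DP permutation p is doubled, two-sided, clipped to
[1/n_perm, 1]; zero-variance tuning curves make the congruency correlation
undefined and raise an error rather than returning NA; depth grids must be
symmetric about zero and are validated; boxcar smoothing shrinks its window
at the trace edges; the discriminant falls back to a Moore–Penrose
pseudo-inverse only when the pooled covariance is singular.

# Limitations

Beyond the generator divergences listed above: the synthetic tuning curves
are unimodal Gaussians over equivalent disparity (the functional form is a
modeling choice, not an empirical claim); spike rasters are homogeneous
Poisson given the trial rate, adequate for boxcar-smoothed time courses but
not for spike-timing analyses; the behavior generator draws conflict levels
uniformly rather than by staircase; and eye movements, pursuit gain, and
rendering are entirely outside scope. The file-format adapter documents how
an external deposit of recorded sessions would map onto the `trials.csv` /
`tuning.csv` schemas, but no download or real-data validation is performed
here.
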