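---
title: "Head-movement synchrony from dyadic accelerometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-movement synchrony from dyadic accelerometry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The analysis in one paragraph

`dyadsync` quantifies how much two people in conversation move their heads
in similar ways at similar times. Each participant wears a head-mounted
3-axis accelerometer sampled at 250 Hz. The raw streams are filtered,
decimated to 10 Hz, collapsed to scalar Euclidean acceleration, and
aligned at a jounce-detected calibration point. Cross-recurrence
quantification analysis (CRQA) then asks, for every relative lag within
±5 s, how often the two movement signals co-visit the same region of a
shared reconstructed phase space; the per-lag recurrence rates form the
diagonal recurrence profile (DRP). A peak at lag 0 indicates synchronous
movement, a U-shape indicates alternation (turn-taking). Growth-curve
analysis (GCA) summarizes each profile by orthogonal linear and quadratic
lag polynomials and models the recurrence rates across the study with a
linear mixed-effects model, against Fourier phase-randomized surrogate
baselines.

## The synthetic-data generator

The package ships a generative model of the whole study, so every
downstream stage is testable without the original recordings.

**Movement model.** Each participant has a latent two-state
(moving/still) bout process at 10 Hz with baseline onset probability 0.03
and offset probability 0.05 per 0.1-s step (movement bouts of roughly 2 s
separated by stills of roughly 3 s, the intermittent nodding-and-stilling
texture of conversational head movement). A latent drive follows an AR(1)
(persistence 0.9 at 10 Hz) pulled toward amplitude 1 while moving; the
drive is interpolated to 250 Hz, multiplied by a band-limited carrier
(AR(1) at 250 Hz, persistence 0.97), projected onto a random fixed axis
orientation per participant, and overlaid with white sensor noise
(SD 0.05). Gravity offset is omitted: all downstream analysis uses
filtered, differenced quantities for which a constant offset is inert.

**Coupling.** Interpersonal coupling enters through the bout processes,
symmetrically so that strong gains do not saturate the duty cycle.
In-phase coupling (gain $g_{in}$): a partner's movement multiplies my
onset probability by $1+g_{in}$ and their stillness multiplies my offset
probability by the same factor — the pair is pulled toward the same
state. Turn-taking coupling ($g_{tt}$) is the mirror image and pulls
toward alternation. The default condition map gives affiliative
conversations strong in-phase coupling ($g_{in} = 8$, $g_{tt} = 0$) and
argumentative conversations turn-taking ($g_{in} = 1$, $g_{tt} = 8$),
identical across task conditions. At these gains the bout correlation is
about +0.65 (in-phase) and −0.5 (turn-taking), which produces the two
canonical profile geometries: an inverted-U with a lag-0 peak, and a
U-shape whose minimum sits at lag 0 with the alternation period inside
the ±5 s window.

**Study frame.** The default design is 21 dyads (9 noise, 12 dual-task),
two 8-minute conversations per dyad with the affiliative/argumentative
order counterbalanced to within one dyad, 250 Hz sampling. Each trace
carries a calibration burst — a 2-s Hann-windowed 1.5 Hz oscillation of
amplitude 10 — planted uniformly at random 60–120 s into the recording,
emulating the rapid nodding/shaking participants perform while testing
the equipment. Server dropout is modeled as exponential censoring with a
per-second hazard; censoring always produces a prefix, never interior
gaps, and a dyad enters the analysis only if all four
participant-conversation traces retain at least 4.5 min (inclusive
bound). The 1 Hz stimulus stream draws blue with probability 0.9 and red
with 0.1, independently each second.

**What the generator does not emulate.** Real head movement has
speech-locked structure, postural drift, gravity reorientation and
occasional sensor artifacts, none of which are modeled; transmission
batching of the acquisition hardware is ignored (traces are emitted at
the full measurement rate). Passing tests on synthetic studies therefore
demonstrate that the *pipeline* recovers planted coupling structure under
realistic sampling, filtering and censoring — not that any particular
empirical effect is true.

## Preprocessing

The preparation chain is, in order: zero-phase 4th-order low-pass
Butterworth anti-alias filter; decimation to 10 Hz; per-sample Euclidean
norm of the three axes; zero-phase 2nd-order Butterworth smoothing;
jounce-based cutoff; trim and truncate.

* **Cutoffs.** The anti-alias cutoff is 5 Hz (the Nyquist frequency of
  the 10 Hz target rate); the smoothing cutoff is 2 Hz, which retains
  nod/shake dynamics (≲2 Hz) while removing sensor jitter. The filter
  orders are analysis constants; the cutoff frequencies are package
  defaults, chosen once.
* **Zero phase.** Each filter is applied forward and backward, which
  cancels the phase response and squares the magnitude response (the
  effective order doubles). Edges are handled with odd-reflection padding
  plus steady-state initial conditions, so a constant series passes
  through unchanged and there is no startup transient.
* **Decimation.** Every k-th sample is retained; non-integer ratios are
  rejected rather than resampled (the generator always produces an
  integer ratio).
* **Derivatives.** Jerk and jounce are central differences scaled by the
  sampling interval, with one-sided differences at the endpoints so
  outputs keep the input length.
* **Calibration cutoff.** Per participant, the cutoff candidate is the
  time of largest |jounce| within 60–120 s (absolute value, ties broken
  by the latest time); the dyad-level cutoff is the later of the two
  participants' jounce cutoffs and is applied to both. After trimming,
  both series are truncated to the shorter length; equal lengths are
  asserted on every run.

## Cross-recurrence

Both series are z-scored, so the recurrence radius is comparable across
dyads. The embedding delay is the first local minimum of average mutual
information (16 equal-width bins); if the AMI curve has no minimum, the
first autocorrelation zero-crossing; failing both, the maximum candidate
lag with a warning. The dimension is the smallest m at which the
false-nearest-neighbor fraction drops below 0.1 (relative tolerance 10;
reference points whose nearest neighbor is farther than half the series
SD are excluded as neighbor-less; exact ties — which arise on noiseless
periodic signals — are resolved by considering all tied neighbors).
Delay and dimension are estimated per series and the pairwise maxima are
shared, since the pair must live in a single phase space.

The radius is the empirical 5% quantile (linear interpolation between
order statistics) of *all* pairwise cross-distances between the two
embedded point sets, so the overall cross-recurrence rate equals the 5%
target; the achieved rate is recounted and reported. No Theiler window is
applied — the two series are different systems, so there is no
line-of-identity to exclude. Distances are Euclidean. The recurrence
matrix is never materialized: overall RR is counted in chunks and the DRP
is streamed per diagonal; both are verified against a naive double-loop
oracle in the tests. The profile spans lags −50..+50 (±5 s at 10 Hz);
positive lag means participant A at time t leads participant B at t+lag.

## Surrogate baselines

Ten Fourier phase-randomized surrogates per conversation are the primary
chance baseline: they keep each series' amplitude spectrum (hence its
autocorrelation) and randomize phases with conjugate symmetry (DC
untouched; for even lengths the Nyquist bin is kept as-is). Both
participants are randomized with independent draws, which destroys
cross-series alignment while preserving each margin's own dynamics.
Surrogates are generated on the trimmed 10 Hz scalar series — the latest
point at which "the same parameters as the real data" is well defined —
and pushed through the identical CRQA pathway with the parent
conversation's delay, dimension and radius, with no re-calibration; their
overall recurrence rate is therefore allowed to drift from 5%. Sample-wise
shuffles are available as a secondary, less conservative baseline.

One subtlety worth knowing: phase randomization Gaussianizes the marginal
distribution, while real movement series are bursty and non-negative, so
the surrogate *level* of recurrence can sit well below the real level
even for uncoupled pairs — the informative comparison is the profile's
lag *structure* (the linear and quadratic terms, which are orthogonal to
the profile's mean level), which is exactly what the contrast models
test. The package's independence checks are therefore phrased in terms of
profile structure, not raw level.

## Growth-curve models

The lag profile is coded by orthonormal first- and second-order
polynomials over the 101 lags (Gram–Schmidt of (1, lag, lag²)): `l` is
odd in lag and captures leading/following asymmetry, `q` is even and
captures curvature (synchrony vs. turn-taking). Conversation is
dummy-coded affiliative 0 / argumentative 1, task dual-task 0 / noise 1.
The full model has the 16-term factorial fixed structure in conversation,
task, `l` and `q`, with random intercepts for dyad and conversation
number. Recurrence rate is modelled as a proportion.

* **Random slopes.** Backward selection starts from a maximal candidate
  set applied identically to both grouping factors and removes one slope
  at a time — highest interaction order first, smallest estimated
  variance first within an order — until the model converges without a
  singular fit; every attempt is logged. The default candidate set is the
  slope structure the deposited-study analysis retained (conversation, `l`, `q`, and the
  task × conversation × `l` interaction); a fully maximal 15-term
  candidate set can be requested, but a 16-dimensional random-effect
  covariance per grouping is not estimable at this study size and the
  walk down from it is pure ritual, so it is not the default.
* **Convergence policy.** A fit counts as converged when the optimizer
  succeeds, no convergence diagnostics fire, and the fit is not singular
  (variance components above 1e-8). Fits that trip lme4's
  gradient/Hessian checks are refitted with bobyqa; if two independent
  optimizers land on the same solution (fixed effects and REML criterion
  agreeing to tight tolerance), the alarm is treated as the false
  positive it is known to be. Because the conversation-number grouping
  has only two levels, its intercept variance frequently sits on the zero
  boundary; a singular intercepts-only fit is accepted as the terminal
  model (with a note in the attempt log) rather than treated as an error.
* **Numerical scale.** Recurrence rates live on a scale of a few
  hundredths, which by itself trips optimizer gradient checks; internally
  the outcome is always centered and scaled for fitting and coefficients
  are mapped back, which leaves t- and p-values untouched.
* **Standardization.** The standardized variant z-scores the outcome and
  scales each predictor by its standard deviation *without centering*, so
  dummy codes keep their reference level, interaction columns remain
  products of their components, and every non-intercept coefficient's
  t-value is identical between the standardized and unstandardized fits.
  This is a convention choice; fully centered z-scoring would change the
  meaning (and t) of lower-order terms in the presence of interactions.
* **Inference.** Estimation is by REML; p-values use the normal
  approximation to t. Post-hoc models refit each conversation type
  separately (task × `l` × `q`, 8 terms; 4 if only one task level is
  present). Contrast models add the surrogate/real factor
  (data = −0.5/+0.5) and all its interactions: 32 terms in the full
  contrast model. Cubic and higher lag terms are out of scope.

## Problem sizes used in the shipped checks

The package's Monte-Carlo checks run at desk scale, chosen once as
representative: parameter-recovery replicates use 21-dyad studies with
180-s conversations (about 60–120 s of analyzed movement after the
calibration cutoff), fixed embedding (delay 5, dimension 4 — the typical
AMI/FNN estimates on these series), 10 phase-randomized surrogates per
conversation, a conversation random slope in the full model and random
intercepts in the contrast model. Twenty seeded replicates recover a
negative, significant conversation effect and a significant
surrogate-contrast curvature interaction at the rates reported by the
test suite. Full-length (480-s) conversations with per-series embedding
estimation behave the same way, only slower.

## Known limitations

* The conversation-number random intercept is estimated from two levels;
  its variance is rarely distinguishable from zero, and with it Eq.-style
  maximal slope structures on that grouping are mostly decorative.
* The delay/dimension estimators are best-practice defaults (AMI first
  minimum, Kennel FNN); other estimators produce somewhat different
  embeddings, and recurrence results should be read as conditional on
  the embedding convention.
* Phase-randomized surrogates test a linear-Gaussian chance model; they
  do not preserve bursty marginals (see above).
* The generator's couplings are stationary within a conversation; real
  synchrony waxes and wanes.
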