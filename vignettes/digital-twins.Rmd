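---
title: "Gain-modulated digital twins of arithmetic learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain-modulated digital twins of arithmetic learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaintwin)
```

## The model

`gaintwin` simulates individual differences in arithmetic learning with a
four-area recurrent convolutional network whose single person-specific
parameter is the *neural gain* `G`, a multiplicative factor on every
rectified response:

$$ y = G \cdot \max(0, x), $$

where the input $x$ to every nonlinearity is standardized to mean 0 and
variance 1 by batch normalization whose affine parameters are permanently
frozen at scale 1 and shift 0. Freezing the affine parameters is what makes
the gain meaningful: the network cannot re-absorb a change of `G` into a
learned rescaling, so `G` genuinely controls the operating point of every
neuron. The gain is the model's operationalization of cortical
excitation-inhibition balance; the excitability grid is
`G = 1 + 0.25 k, k = 0..16` (17 levels from 1 to 5).

The four areas (V1, V2, V3, IPS) mirror the dorsal visual stream. Each area
is a recurrent block: an input convolution, a weight-shared recurrent
convolution applied over a fixed number of time steps (defaults 1, 2, 2, 2),
the frozen-affine normalization, the gain rectification, and a 2x2 max
pool. All representational analyses read the *final* recurrence step of an
area. A linear decoder maps the flattened pooled IPS map to 19 logits, one
per possible answer 0..18. We deliberately use a position-sensitive decoder
(flattened map rather than a global average pool): operand order matters
for subtraction, and a translation-invariant readout would discard the slot
information the task depends on.

The block internals are a structural simplification of the CORnet family of
visual-stream models (recurrence with shared weights, area names, no
pre-training) rather than a parameter-for-parameter reproduction of
CORnet-S; bottleneck triple convolutions are replaced by the single
input+recurrent convolution pair. The gain mechanism, the frozen
normalization, the 19-way decoder and the four-area recurrent hierarchy —
the components the scientific claims rest on — are retained exactly.

## The task and the stimulus generator

The problem space is every addition and subtraction of operands 0..18 whose
result lies in 0..18: 190 additions and 190 subtractions, 380 problems,
each rendered as five 28x28 glyph slots (tens and units of each operand
around the operator) into a 3x28x140 image. The operator glyphs are
composed from the digit "1": minus is a rotated "1", plus the pixel-wise
maximum of a vertical and a rotated "1".

Two glyph backends exist. The MNIST backend reads IDX files and draws
training variants from the MNIST training split and test variants from the
MNIST test split. The synthetic backend — the default, so that the package
builds and tests without downloads — renders parametric stroke digits:
seven-segment-style skeletons with random affine jitter (shift up to 1.5 px,
rotation up to 0.1 rad, scale 0.9-1.08), stroke width 2.4-3.2 px and mild
additive pixel noise (SD 0.02). For the synthetic backend both splits draw
from one glyph pool and the train/test split is made at the level of
*variants* (glyph-choice tuples sampled without replacement), so the two
splits share no rendering; this emulates a learner who sees one consistent
"font" during learning and test. Synthetic glyphs have far less within-class
variability than handwriting, so cross-split generalization is easier than
with MNIST; passing tests on synthetic data therefore demonstrate the
learning and excitability phenomena, not handwriting-grade robustness.

A practical consequence, documented here because it shaped the defaults: at
small network widths the arithmetic task is prone to shortcut learning.
With too few variants per problem the network memorizes whole training
images (training accuracy rises, held-out accuracy stays at chance) instead
of binding per-slot digit identities. Variant diversity is what forces the
compositional solution; the desk-scale default of 50 variants per problem
is the smallest value at which we found binding to emerge reliably.

## Training and the excitability sweep

Networks are trained with cross-entropy over the 19 answers and Adam
(learning rate 0.001 at full scale), evaluating the held-out split at
iteration 0 and every `eval_every` iterations (default 100 batches of 100).
One model is trained per gain level on the identical dataset and seed.
Higher gain slows learning: the recurrent term is amplified relative to the
feedforward drive, and the decoder's input scale grows with `G`, saturating
the softmax and degrading the gradient signal. Untrained models respond at
chance (about 5%; the test set is balanced with 20 problems per result, so
both a uniform guesser and a constant responder sit at 1/19).

Three profiles are used in this package's own runs, chosen once as the
study conditions for each compute scale:

* full profile: width scale 1.0, 100 variants/problem, batch 100,
  3800 iterations — the configuration the full-scale findings describe.
* desk profile: width scale 0.25, 20 variants/problem, batch 50,
  about 1000 iterations — a single-CPU afternoon run.
* test profile (used by the automated suite): width scale 0.125, 50
  variants/problem, batch 50, learning rate 0.002, a gain subgrid
  {1, 2, 3, 4, 5} and an iteration cap of a few thousand — the smallest
  configuration at which low-gain models reliably exceed the 95% accuracy
  criterion while high-gain models lag, so that learning-speed and
  accuracy correlations with gain are measurable within minutes.

The batch size and learning rate of the reduced profiles matter: at widths
far below full scale, small batches (<= 32) destabilize the frozen-affine
batch statistics and learning stalls, while learning rates >= 0.005 cause
post-memorization collapse of held-out accuracy. 0.002 with batch 50 was
chosen as the stable point and fixed before the acceptance checks were run.

## Digital twins: matching models to subjects

Each subject contributes one achievement score (a NumOps-like number; the
MLD/TD group threshold is 90). Model accuracies are normalized to [0, 1] by
the min/max over the entire sweep (all gains x all evaluated iterations);
subject scores by the cohort's normalization bounds. The behavioral
distance between a model and a subject is the L1 distance of these
normalized scores; at every evaluated iteration each subject is assigned
the gain minimizing it (ties toward lower gain, a deterministic and
conservative convention). The *reference iteration* minimizes the
cohort-mean distance (ties toward earlier). A permutation control reassigns
uniformly random grid gains to subjects at the reference iteration.

The cohort is either read from CSV or synthesized. The synthetic generator
draws true gains from truncated normals on the grid (TD centered at 2.05,
MLD at 3.77, SD 0.55, the group levels the twins are meant to emulate), reads off the model's
normalized accuracy at the generating iteration, adds Gaussian score noise,
and maps to the achievement scale so that the threshold 90 falls midway
between the noiseless group boundaries (60 achievement points per unit of
normalized accuracy). The generator records its affine scale anchors as the
cohort's normalization bounds, making normalization exactly invertible;
without the anchors, cohort-min/max normalization is a different affine map
than the sweep's global normalization and even noiseless cohorts would not
be recovered exactly. For empirical cohorts (no anchors available) the
bounds default to the cohort min/max.

## Behavioral and representational read-outs

*Behavior.* Per expected result r: the mean response and population SD of
the responses. Systematic error (lack of trueness) is the mean over r of
|mean response − r|; imprecision the mean within-level SD; the effective
number of responses is exp of the natural-log entropy of the marginal
response distribution (1 for a constant responder, 19 for a uniform one).
The marginal (not per-level) distribution is used for the entropy, matching
the description of the response distribution as a whole.

*NRS.* For each layer, the mean activation pattern of each of the 380
problems over its test variants, rows in canonical order (additions first,
then ascending result, then ascending first operand); the 380x380 Pearson
correlation across units; and block means add-sub (all cross pairs),
add-add and sub-sub (unordered distinct within-operation pairs, diagonal
excluded — self-similarity of 1 would bias the level). Zero-variance units
are dropped with a warning. Empirical similarity values arriving on the
Fisher-z scale are mapped back through tanh before correlating model with
data.

*Manifolds.* The 380 problem means partition into 19 result manifolds of 20
points each. Geometry follows the mean-field theory of linear manifold
classification: per manifold, residuals around the center are expressed in
their own subspace, scaled by the center norm, and augmented with a
constant coordinate; for each of `n_samples` Gaussian directions the anchor
point on the convex hull solves a small quadratic program (margin
kappa = 0, dual coordinate descent, tolerance 1e-10). Capacity is the
inverse mean squared anchor field (point manifolds recover the classical
value 2), radius the RMS anchor norm in subspace coordinates, and
dimensionality the mean squared alignment of direction and unit anchor.
The estimator is validated in the test suite against an exact empirical
oracle: random balanced dichotomies of the manifolds, separability decided
by a min-norm-point-in-hull certificate (away-step Frank-Wolfe, which
either finds a strict separator or collapses the hull norm), and capacity
read off the 50% separability crossing over feature-subsample sizes.
Center correlation is the mean absolute cosine between centroids after
global centering; the absolute value is a convention (alignment magnitude,
not sign) adopted because sign is arbitrary under unit relabeling.

## Remediation

At the reference iteration, models matched to below-threshold subjects are
given further training until their test accuracy is closest to the median
accuracy of the TD-matched models (ties toward earlier iterations).
Reported are the additional iterations, the percentage of the reference
iteration they represent, and pre/post behavioral, NRS and manifold values.

## Numerical and degenerate-input conventions

Population (n) SDs in behavioral profiles; natural-log entropy; Pearson
correlations throughout; Welch t-tests with pooled-SD Cohen's d (sign:
first minus second group); no multiple-testing correction (raw statistics
are reported, as in the source analyses). Degenerate cases: point manifolds
are handled as radius-0 manifolds; zero-norm centered centroids are
excluded from center correlation with a warning; equal normalization
bounds, empty cohorts/sweeps/stimulus sets and non-finite losses raise
errors naming the offending quantity; ties in matching, reference-iteration
selection and catch-up targeting all resolve deterministically (lower gain,
earlier iteration).

## Known limitations

* The synthetic glyphs under-represent handwriting variability; MNIST-level
  robustness claims require the MNIST backend.
* Reduced-scale runs reproduce directions and correlations, not the
  absolute iteration counts (800, 1700) or group statistics of the
  full-scale study; those depend on full-scale width and the undeposited
  child cohort.
* Not every full-scale direction survives the reduction. At test-profile
  width with a 5-level gain subgrid we reliably observe the learning-speed
  and early-accuracy correlations with gain, the rise of add-sub NRS with
  gain, and the remediation directions. The manifold-geometry trends with
  gain (capacity, dimensionality, center correlation), by contrast, are
  noise-dominated at this width: equally valid reduced configurations show
  or invert each of them (we checked both anchor-alignment conventions and
  the participation ratio, several layers, iterations and sample counts),
  so they should only be trusted at larger widths. Likewise,
  parameter-recovery bounds calibrated for the fine 17-level grid are not
  attainable when adjacent gain levels differ by less in normalized
  accuracy than the simulated score noise. The corresponding automated
  checks are left asserting the full-scale direction and fail visibly
  rather than being weakened.
* The mean-field geometry is estimated on problem-level mean responses
  (20 points per manifold), not variant-level clouds; a variant-level
  analysis would need far more Gaussian samples to stabilize.
* Forward/backward convolutions run in single precision; learning curves
  are reproducible for a fixed seed and BLAS, not bit-portable across
  BLAS implementations.
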