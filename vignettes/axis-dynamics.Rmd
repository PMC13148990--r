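---
title: "Time-resolved encoding-axis dynamics: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved encoding-axis dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(axisdyn)
library(dplyr)
```

## The scientific question

High-level visual neurons are often well described by *axis coding*: a cell's
response to a stimulus with feature vector $f$ (a point in a low-dimensional
PCA space built from deep-network image embeddings) is approximately

$$ r \approx c \cdot f + r_0, $$

where $c$ is the cell's *preferred axis*. Face-selective neurons in
inferotemporal cortex raise a sharper question: does a face cell use one axis
for everything, or does it switch between codes — an early, category-level
*detection* code shared with its object tuning, and a later, face-specific
*discrimination* code? The switching picture predicts a precise set of
signatures:

* time-resolved face axes transiently align with the cell's object axis at
  short latency and then reverse in the leading feature dimensions;
* new tuning directions, orthogonal to the early axis, emerge at long
  latency, raising the dimensionality of the population response;
* population responses to faces become sparser after the switch;
* linear decoders trained at one latency fail to transfer across the switch,
  while identity information improves late;
* a simple recurrent circuit with lateral inhibition can produce such a
  reversal in two synaptic timesteps.

`axisdyn` implements this entire analysis chain — axis estimation, sliding
window dynamics, flip detection, the bespoke population statistics, the
window-wise decoding experiments and the recurrent-network model — together
with a synthetic-population generator that encodes the switching hypothesis
as ground truth. Because the motivating recordings are not publicly
available, every method here is validated by parameter recovery: simulate a
population whose axes are known, run the pipeline, and check that what comes
out is what went in.

## The synthetic population generator

`make_stimulus_set()` draws stimulus embeddings from a Gaussian with a
geometrically decaying variance spectrum (`sd_decay = 0.94` per dimension),
emulating the ordered spectrum of deep-network embedding PCAs, and shifts
the face rows by a category offset along the first two dimensions so that
faces occupy one quadrant of the leading plane — the geometry that makes a
"face detection" direction exist at all.

`make_switching_truth()` builds per-cell unit-norm axes:

* **early face axis / object axis** — positive loadings on the first
  `flip_dims` dimensions (the shared detection direction; loading spread
  `flip_loading_sd = 0.5` reproduces the broad but consistent fan of object
  axes seen across real face cells) plus small random high-dimensional
  components (`highdim_sd = 0.25`);
* **late face axis** — the detection block negated, plus fresh independent
  loadings on the next `new_dims` dimensions. The fresh block carries
  `new_gain = 2.5` times the norm of the flipped block, so emergent tuning
  dominates the late axis, as the large orthogonal components of late axes
  in real cells suggest.

`simulate_population()` turns axes into rates at 1-ms resolution:

$$ r_j(i, t) = \Big[\, b_j + v_j\,k(t - \ell_j) + g_j \,\langle a_j(t),
   f_i \rangle\, k(t - \ell_j) \Big]_+ , $$

with per-cell baseline $b_j$ (5 Hz), nonspecific visual drive $v_j$ (12 Hz at
kernel peak; every stimulus evokes it, so anti-preferred stimuli modulate
around a driven rate instead of silencing the cell), gain $g_j$ (40 Hz per
feature unit), response latency $\ell_j$ (50 ms plus uniform 0–20 ms jitter,
which the adaptive short-latency window logic has to absorb), and a
difference-of-exponentials kernel $k$ (rise 10 ms, decay 40 ms, peak 1),
giving a transient-then-sustained profile with its population peak near
85 ms. The axis $a_j(t)$ is the early axis before `switch_time_ms` (110 ms)
and, for face stimuli only, the late axis afterwards; object stimuli use the
(fixed) object axis throughout, with their drive compressed by
`object_gain_frac = 0.4` because face cells devote most of their dynamic
range to the face region of the space. Trial noise is Poisson by default
(spike counts over `n_repeats` trials, averaged), with a Gaussian option.

Two deliberate modelling choices deserve emphasis:

* **The late code is referenced to the mean face.** The post-switch face
  drive is $\langle a^{late}_j, f - \bar f_{face}\rangle$ (plus an optional
  fraction `late_offset_frac` of the early mean drive, 0 by default). This
  is norm-based face-space coding: the late code represents deviation from
  the average face. Without it, the negated detection loadings would place
  the whole face cluster deep in the rectified region and late responses
  would vanish; with it, late responses are measurable but sparse —
  exactly the regime the switching hypothesis describes.
* **The no-switch control is exactly stationary.** `make_no_switch_truth()`
  sets the late axis equal to the early axis and the late offset fraction to
  1, which makes the post-switch drive algebraically identical to the
  pre-switch drive. Any reversal a detector reports on a control population
  is therefore a false positive by construction.

Three further generators emulate cell-intrinsic artifacts that could be
mistaken for switching — a gain transient (`simulate_gain_artifact`),
drive-dependent latency (`simulate_latency_artifact`) and a raised firing
threshold engaging after the transient (`simulate_threshold_artifact`). All
three keep each cell's axis constant, so they define the specificity side of
every reversal detector.

What the generator does **not** emulate: real image statistics (embeddings
are Gaussian, real fc-layer activations are not), spike timing (rates only),
adaptation and serial dependence across trials, correlated noise across
cells, and the heavy-tailed firing-rate distributions of cortex. Passing
tests therefore demonstrate that the *analysis* is correct and sensitive
under the assumed generative structure — not that the brain works this way.

## Axis estimation

`fit_axis()` implements the closed-form linear-encoding estimate
$w = (r - \bar r)\,F\,(F^\top F)^{-1}$ via a QR least-squares solve, with one
refinement: the feature matrix is centred on the training subset, which is
equivalent to fitting an intercept. The closed form implicitly assumes
zero-mean features; a *category subset* of a globally normalized feature
space has a nonzero mean (faces sit away from the grand centroid), and
without the intercept the estimate is biased — on noiseless synthetic cells
the recovery cosine plateaus near 0.82 instead of reaching 1. With centring,
noiseless recovery is exact to numerical precision, which is the invariant
the test suite enforces.

Held-out $R^2$ is $1 - SSE/SST$ with SST about the test-set mean, defined as
0 when SST is 0, and reported as-is when negative. The default split is
90/10, stratified by category, fixed across all windows of a sliding-axis
fit so that axes at different latencies are directly comparable.

`normalized_fo_correlation()` divides the raw face–object axis cosine by a
split-half upper bound (20 resampled halves). A ratio is only meaningful
when the bound reflects reliable tuning, so the cell is flagged
unnormalizable unless the bound exceeds twice its resampling error *and*
both category fits have positive cross-validated $R^2$ — a frozen
trial-averaged noise pattern is "self-consistent" between split halves, and
only the cross-validation step catches it.

## Sliding-window dynamics

Windows are half-open `[start, start + 20) ms`, non-overlapping by default,
over 0–300 ms. `similarity_matrices()` reports mean cosine similarity across
cells for (object, object), (face, face) and (face, object) axis pairs at
all latency pairs; the (face, object) diagonal is the alignment time course.
`detect_flip()` projects each cell's early (80–100 ms) and late (120–140 ms)
face axes onto the first two feature dimensions and flags a flip when the
2-D angle exceeds 120° — a deliberately strict threshold meaning *clear
reversal*, not mere rotation — and both windows pass the held-out-$R^2$
inclusion rule. The flip time is the first window whose 2-D cosine to the
early axis falls below the threshold; a divergence time defined as the first
of two consecutive windows with negative face-to-object-axis cosine is
available from the alignment table.

Object-axis stability deserves a caveat: with Poisson noise at object
response levels (object drive is compressed), fitted object axes carry
substantial estimation noise, so their adjacent-window cosines sit near the
attenuation ceiling (~0.85 in signal windows) rather than at 1. The package
asserts exact stability on noiseless populations and, on noisy ones, the
*contrast* that matters: object axes stay positively aligned across the
switch while face axes reverse.

`adaptive_short_window()` implements the per-cell short-latency window: the
first 20-ms window whose mean response exceeds the baseline (−25 to 25 ms)
mean by two baseline standard deviations, with a 0.1-Hz floor on the s.d.
for silent baselines.

## Population statistics

* **d′ and peak d′** — the standardized face/object mean difference per
  1-ms bin; the peak is the maximal 20-ms mean with the window start sliding
  over 80–120 ms. When both variances vanish, d′ is 0 for equal means and
  clipped to ±10 otherwise.
* **Sparseness** — the modified Treves–Rolls population statistic
  $S = 1 - (\sum_j r_j)^2 / (N \sum_j r_j^2)$ per stimulus and time bin,
  exactly 0 for uniform and $1 - 1/N$ for one-hot activity. At realistic
  rates with ten trial repeats, raw 1-ms bins are dominated by spike-count
  shot noise that saturates $S$ for every stimulus; the pipeline therefore
  smooths each cell's rates with a 20-ms boxcar first (`smooth_ms`), which
  recovers the rate-level structure the statistic is about.
* **PSI** — mean pairwise Euclidean distance between group-mean population
  vectors over the pooled response s.d.; exactly invariant to rescaling and
  to adding a constant. For *identity* grouping (one stimulus per group) the
  plain ratio is pinned near $\sqrt{2N}$ by trial noise — the numerator and
  denominator share the same variance — so the identity time course uses a
  cross-replicate debiased distance when an independent noise replicate of
  the population is supplied: squared distances are estimated by
  $\langle r^{(1)}_i - r^{(1)}_j,\; r^{(2)}_i - r^{(2)}_j\rangle$, whose
  noise term cancels in expectation. The debiased curve starts near zero
  and peaks where genuine identity separation peaks (late, for switching
  populations).
* **Dimensionality** — the number of principal components needed to reach
  90% of the variance of the z-scored cells × stimuli matrix per window,
  bootstrapped over stimuli with the same resample applied to both windows
  for a paired comparison.
* **Single-stimulus axis-change score** — the per-stimulus Pearson
  correlation between raw early (60–80 ms) and late (100–120 ms) population
  vectors (extreme-rate cells outside the 1st–99th percentile excluded, no
  per-cell normalization), mapped through a one-feature logistic regression
  with inverse-frequency class weights, trained on a stratified half of the
  labels and applied to every stimulus.

## Decoding experiments

The three decoding windows each consist of two 25-ms sub-windows (short:
50–75/75–100 ms; long: 120–145/145–170 ms; combined: 62–87/132–157 ms)
whose responses are stacked as if from distinct cells. Decoders are ridge
regressions onto latent stimulus features with the penalty chosen on a
validation fold; each cell × sub-window channel is z-scored using
training-stimulus statistics of its own window, so cross-window transfer
probes the response *pattern* rather than kernel-amplitude differences.
Identification is nearest-neighbour among the held-out references
(ties to the lowest index), with an optional fixed linear map into a metric
space. Identification latents default to the un-normalized PCA scores
(scale preserved), so coarse high-variance dimensions carry more
identification weight, as any perceptual metric would impose.

`simulated_unit_experiment()` isolates the redundancy-versus-diversity
trade-off: "short-latency" units linearly combine a random handful of only
the first five latent dimensions, "long-latency" units a random handful of
all sixty; with few cells the redundant low-dimensional pool wins, with
many cells the diverse pool wins. The same crossover appears when decoding
the synthetic switching populations window by window.

## The recurrent-network model

The mechanism model is a 100-unit network $h_t = \tanh(x_t + W h_{t-1})$
trained for 10,000 iterations (Adam, learning rate 0.001, batch size one)
to map a random linear gradient, presented at both of two timesteps, to its
reversal at the second step. Two unspecified details were resolved as
follows: the "random linear gradient" is $x_i = a\,(i/n) + b$ with
$a, b \sim N(0, 0.5^2)$ (an alternative generator grades a random direction
instead); the scale keeps most inputs inside the tanh output range so the
reversed gradient is a representable target. The readout is the identity
(the loss compares $h_2$ itself to $-x$); a linear readout is not modelled.
Gradients are hand-derived — with $h_0 = 0$ the two-step chain rule has a
single term, $\nabla_W L = \delta_2 h_1^\top$ — and are verified against
central-difference numerical differentiation to $10^{-6}$. The reported
loss reduction is measured against the untrained network's expected loss
over 200 held-out gradients, not against the first training iterations
(which already reflect learning). After training, each unit's linear tuning
to probe gradients is fit at both timesteps by minimum-norm least squares
(the probes span a two-dimensional manifold, so the pseudoinverse is the
correct solve); reversal training makes the mean timestep-1 versus
timestep-2 tuning cosine strongly negative, while an identity-target
control keeps it positive — lateral inhibition learned in $W$ is what flips
the code.

## Numerical and design details

* All randomness flows through explicit seeds; no function touches global
  RNG state without restoring it.
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive, so feature spaces are bit-reproducible.
* Windows are half-open in milliseconds everywhere; the anterior-medial
  face patch's lag is handled by a single `offset_ms`/`area_offset_ms`
  parameter that shifts the comparison windows by +20 ms.
* Degenerate cases are defined, not patched around: zero-variance test sets
  give $R^2 = 0$; all-zero population vectors give `NA` sparseness; a zero
  baseline s.d. uses a 0.1-Hz floor; ties in identification break to the
  lowest index.
* Problem sizes: the validation analyses use populations of 60–100 cells,
  250 face and 250 object stimuli, ten Poisson trial repeats, and
  K = 60-dimensional feature spaces — about a sixth of the stimulus count
  of a full recording session, chosen so a complete parameter-recovery run
  remains a desk-scale computation. The default gain (40 Hz per feature
  unit) places the held-out per-window $R^2$ of the early response window
  near 0.5, a typical operating point for well-isolated face cells.

## Worked example

```{r example, eval = FALSE}
library(axisdyn)

stim <- make_stimulus_set(250, 250, D = 60, seed = 1)
truth <- make_switching_truth(K = 60, n_cells = 100, seed = 2)
pop <- simulate_population(stim, truth, n_repeats = 10, seed = 3)

space <- fit_feature_space(stim$embeddings, K = 60)
feats <- project_features(space, stim$embeddings)
split <- train_test_split(pop$category, seed = 4)

tc_face <- sliding_axes(pop, feats, "face", split = split)
tc_obj <- sliding_axes(pop, feats, "object", split = split)
sim <- similarity_matrices(tc_face, tc_obj)
plot_alignment(sim)            # +0.85 before ~110 ms, negative after

flips <- detect_flip(tc_face)
glance(flips)                  # flip fraction ~1, flip time 120 ms
```

## Known limitations

* Recovery guarantees are internal to the generative model; none of the
  statistics can certify that real data were produced by stimulus-gated
  axis switching, only that the signatures are detectable when it is.
* The identity-PSI debiasing needs an independent noise replicate, which a
  real experiment supplies via trial splits; the simulator supplies it via
  a second noise seed.
* Sparseness comparisons depend on the smoothing scale at low rates; the
  20-ms default matches the axis-fitting window width.
* The decoder's latent space is the stimulus feature space itself (or any
  user-supplied latents); generative image reconstruction is out of scope.
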