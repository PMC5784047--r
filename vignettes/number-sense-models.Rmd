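---
title: "Models and methods: how numerosense simulates the emergence of number sense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(numerosense)
```

numerosense implements two complementary computational accounts of how an
approximate number sense (ANS) — the ability to compare visual numerosities
with ratio-dependent precision — can arise without any number-specific
supervision:

1. a **deep generative network** whose first processing stage is hard-wired
   visuospatial machinery, whose second stage learns an unsupervised
   generative model of object-set images, and whose behaviour is read out by
   a minimal associative (delta-rule) layer; and
2. an **artificial-life ecosystem** in which recurrent-network foragers
   evolve under a genetic algorithm whose only objective is the rate of food
   collection, and are then tested on explicit quantity-comparison trials.

This vignette documents the models, every consequential design decision, the
numerical choices, and what the bundled synthetic data can and cannot show.

## Stimulus generator

Stimuli are `side x side` (default 30 × 30) binary images containing `N`
disjoint axis-aligned rectangles (1 ≤ N ≤ 32). Ground truth is carried with
each image: numerosity `N`, cumulative area `A` (total on-pixels), contour
length `C` (on-pixels with at least one off 4-neighbour), and per-item
areas. Objects are separated by at least one pixel in every direction
(including diagonals), so `N` always equals the number of 4-connected
components; `count_objects()` is the package's counting oracle, and the test
suite re-verifies every generated image against an independent flood-fill
and an external image-analysis labeller.

Design choices, and why:

* **Cumulative-area levels** default to {32, 64, 128, 256} pixels, sampled
  independently of `N` within feasibility. Decorrelating `A` from `N` is
  what makes numerosity a *statistical invariant* that unsupervised learning
  has to discover rather than inherit from a confound.
* **Item sizes** are a near-equal partition of `A` into `N` parts with
  multiplicative jitter (log-SD 0.25), items compact (aspect close to
  square) and bounded at 8 pixels a side. This emulates standard dot-array
  displays: dot sizes within a display are homogeneous-with-jitter and
  bounded, while cumulative area varies across displays. The bound also
  constrains which area levels a given `N` can realise (mean item area at
  most 32 px), so very small numerosities use the smaller area levels —
  as in displays where one enormous object filling a quarter of the screen
  would not occur.
* **Congruency-controlled pairs** are built by the *same* generator; only
  the assignment of area levels relative to numerosity is manipulated.
  Congruent: the more numerous image also gets the higher area level and
  larger mean item size (which drags contour along). Incongruent: the more
  numerous image gets a lower area level, smaller items and less contour.
  Every emitted pair is verified by recomputing all three continuous
  properties from the pixels; unsatisfiable requests fail with an explicit
  infeasibility error. Partial congruency (manipulating one property at a
  time) is deliberately out of scope.
* Placement is rejection sampling with a retry cap, then an explicit
  placement-failure error — never a silently wrong count.

What the generator does **not** emulate: grayscale or natural images,
density/convex-hull control, occlusion, or item shapes beyond rectangles.
Conclusions from passing tests therefore concern this controlled stimulus
family, not natural scenes.

## The deep network

### Fixed first stage: filters plus pooled summation channels

The first hidden layer is fixed — the model's stand-in for innate
visuospatial machinery — and has two parts.

*Centre-surround filters.* Balanced difference-of-Gaussians kernels
(on-centre and off-centre at every anchor of a stride-2 tiling) at four
receptive-field scales (centre sigma 0.5, 1, 2, 3.5 px; surround twice the
centre). Retinal ganglion and LGN receptive fields come in exactly such a
range of sizes and mature without visual experience. Each kernel's weights
sum to zero (uniform fields elicit nothing) and its positive lobe is
L1-normalised, so rectified responses lie in [0, 1]. A scale's kernels act
as blob/edge detectors matched to items of that size.

*Pooled summation units.* Per scale channel, a small population (24 units)
monotonically pools the channel's total rectified activity through
logarithmically spaced soft thresholds — a thermometer intensity code with
Weber–Fechner compression, baseline-subtracted so a blank image yields
all-zero features. These units carry compressed aggregate signals (how much
contour/area energy at each spatial scale); they cannot by themselves
encode numerosity, which requires *combining* channels: the count of items
is approximated by summing scale-channel activity normalised by the
area-per-item that each scale implies. Threshold populations are the
standard neural way to make a scalar magnitude available to downstream
linear read-outs, and log-compressed magnitude codes are ubiquitous in
early sensory systems. Without this component, numerosity information is
present in the anchor responses but only in a form a linear read-out cannot
reach (it requires log-ratio arithmetic across channels).

### Second stage: unsupervised generative layer

A restricted Boltzmann machine with 400 stochastic binary hidden units over
the 1 896 first-stage features, trained by single-step contrastive
divergence (learning rate 0.05, momentum 0.5 → 0.9 after 5 epochs, weight
decay 2e-4, minibatch 100). The training interface receives pixels only —
labels are not an argument — and the suite asserts bit-identical results
when all metadata is deleted. "Initial network" means this layer at its
random Gaussian initialisation (SD 0.3); "mature network" means the layer
after unsupervised training. Encoding for analyses and read-out uses
deterministic mean-field probabilities so neuron-level statistics are
reproducible; sampling noise would otherwise contaminate tuning analyses.

Checkpoints are stored every 30 epochs. The scaled profile trains 90 epochs
on a 5 000-image corpus; the full profile mirrors the reference regime
(51 200 images, 300 epochs) and is correspondingly heavier.

### Read-out

The comparison task is two-alternative: which side of a pair has more
items? The read-out applies a single learned evidence template `v` to each
side's hidden representation and compares the two evidence values —
equivalently a linear-logistic unit on the difference of the two hidden
vectors, trained online by the delta rule (Rescorla–Wagner; learning rate
0.05, 30 presentations of the feedback set). We chose the tied-template
form over an unconstrained weight matrix on the concatenated pair because
the task is symmetric under left–right exchange: tying enforces that
symmetry structurally, halves the parameters, and is how matched-template
comparison is usually modelled. Feedback scarcity is modelled by
`feedback_fraction` (default 0.25) or an absolute `n_feedback`, so both a
"25% of pairs" and a "184 pairs" regime are expressible. Read-out training
never modifies generative-layer weights, and the suite asserts it.

## Psychophysics

Accuracy is tabulated per exact numerical ratio `r = min(N1, N2) /
max(N1, N2)`. The psychometric model is the standard ANS form

$$p(\text{correct} \mid r) = \Phi\!\left(\frac{|\ln r|}{\sqrt{2}\, w}\right),$$

a cumulative normal in log-ratio with the Weber fraction `w` as its single
parameter (lapse rate fixed at 0 by default, configurable). `w` is fitted
by least squares over the ratio table; noiseless tables invert to machine
precision and parameter recovery under binomial trial noise is part of the
test suite (w in {0.1, 0.2, 0.35}, 1 000 trials per ratio, ±15% relative
error). Fits where all accuracies sit at chance or ceiling are flagged
`unreliable` rather than reported silently. Developmental trajectories
retrain the read-out identically at every checkpoint (same pairs, same
seed) and evaluate on a frozen pair set disjoint from the feedback pairs,
so the trajectory reflects the representation, not the read-out or
train/test leakage.

Comparison pairs span ratios 1:2, 2:3, 3:4, 4:5, 5:6, 6:7. The scaled
profile uses 800 pairs per ratio for the feedback pool and 250 per ratio
for evaluation.

## Neuron-level coding analyses

Hidden units are probed with factorial corpora crossing numerosity with
cumulative area.

*Summation coding (numerosity-sensitive units).* Per unit, ordinary least
squares of the standardized cell-mean activation on standardized `log2 N`
and `log2 A` over a 1–32 × {32, 64} probe (20 images per cell). A unit is
sensitive when `|B_N| ≥ 0.10`, `|B_A| ≤ 0.05` and R² ≥ 0.5; the sign of
`B_N` separates increasing from decreasing profiles. The two area levels
are the ones feasible across the entire 1–32 numerosity range under the
bounded item size. Thresholds are configurable; the defaults are the
package's own, chosen once as "large numerosity coefficient, small area
coefficient, good fit" in standardized units.

*Numerosity selectivity.* Per unit, a balanced two-way ANOVA (numerosity ×
area, with interaction) over per-image activations of a 1–5 × {32, 64} ×
50-replicate probe. Selective = significant numerosity main effect at
alpha = 0.01 with neither an area effect nor an interaction at that level;
the preferred numerosity is the marginal-mean peak. The implementation is a
closed-form balanced decomposition vectorised across units; the suite
checks it against `stats::aov` to 1e-8. No multiple-testing correction is
applied across units — selection is per-neuron, as in the
electrophysiological analyses this mirrors — and that choice is explicit
rather than silent. Tuning curves of selective units are min–max normalised
to [0, 1], pooled by preferred numerosity, re-indexed by numerical distance
from the preferred level, and tallied into a preferred-numerosity frequency
distribution.

Both classifiers accept planted activation matrices, and the suite verifies
≥95% recovery of planted coding types at noise SD 0.02 as well as
permutation invariance.

## The artificial-life ecosystem

A 100 × 100 grid of cells holding food quantities 0–9, with a fixed
population of 200 agents. Each agent is a recurrent, asymmetrically
connected network: 36 sensory units (the current cell plus the three cells
of the row directly ahead, each cell's quantity `n` coded as `n` randomly
chosen active units among 9 — a size-free quantity code), an evolvable
hidden layer of 2–20 logistic units, and 4 effectors (turn left, turn
right, move forward, eat) selected by argmax with random tie-breaks.

Design decisions:

* **Field of view.** "The current cell and the three cells directly ahead"
  is implemented as the full row ahead (ahead-left, ahead, ahead-right)
  plus the current cell — the only reading under which an agent at the
  centre of the 3 × 3 test arena can sense both baited corner cells, as the
  test requires.
* **Sparse food.** A cell is empty with probability 0.75, otherwise holds a
  uniform quantity 1–9. Eaten cells refill after a fixed 100-iteration
  delay; a refill that draws 0 schedules another draw, so the food supply
  is stationary (a rate-based fitness stays meaningful indefinitely).
  Sparseness matters: in a saturated world, blind "eat and step forward"
  foraging is optimal and no selection pressure for sensing-guided steering
  — the behavioural substrate of quantity comparison — exists.
* **Walled grid.** The world has walls, like the test arena, rather than a
  torus. On a torus, straight-line strip-farming is a sensing-free local
  optimum (an agent cycles its own regrowing trail forever); walls force
  turning and reward food-directed steering.
* **Genetic algorithm.** Each iteration, after all agents act, two distinct
  parents are drawn uniformly from agents past a 500-step burn-in; the one
  with the lower lifetime food-collection rate is replaced by the pair's
  child (uniform per-gene crossover; additive Gaussian mutation SD 0.1
  with per-gene probability 0.03; hidden size inherited from a random
  parent with a ±1 mutation at probability 0.02, clamped to [2, 20]).
  Population size is invariant by construction and asserted after every
  run. The mutation scale matters: an order of magnitude weaker mutation
  (SD 0.05 at probability 0.01) leaves the population without any arena
  choice behaviour even after several million iterations, because uniform
  crossover between unrelated genomes supplies too little usable variation
  on its own.
* **Test battery.** Every ordered pair of distinct quantities from 1–9
  (72) × 50 repetitions = 3 600 trials per agent. The agent starts at the
  arena centre facing the baited row and chooses by stepping onto a baited
  corner; response time is the number of steps; trials hitting the 50-step
  cap are recorded as timeouts and excluded from accuracy. A greedy oracle
  policy and a uniform-random policy are built into the battery as
  bookkeeping ground truth and chance baseline.

The scaled evolution profile runs one million iterations — comfortably past
the horizon (about 0.6 million under the default mutation settings) at
which food-directed steering, and with it arena choice behaviour,
consolidates in the population. Full convergence takes several million
iterations; population-level proportions (such as the share of
non-discriminating agents) measured at the scaled horizon are
horizon-dependent and are reported as such.

## Reproducibility

Every stochastic stage takes an explicit seed; experiment recipes
(`run_experiment()`) derive per-stage sub-seeds deterministically from one
master seed and write a JSON manifest (resolved configuration, sub-seeds,
package version) alongside their TSV outputs, sufficient to re-run
bit-identically. The evolife core draws all randomness from R's RNG (via
the C++ `unif_rand`/`norm_rand` interface), so `set.seed()` governs the
compiled loops too.

## Known limitations

* The stimulus family is rectangles on a small binary grid; density and
  convex hull are uncontrolled beyond what area/contour/item-size control
  implies.
* The first-stage pooling populations are hard-wired; a more realistic
  model would let early spatial acuity itself develop.
* Single-layer generative training: the filter stage never learns
  (joint multi-layer development is out of scope).
* Scaled-profile results are desk-scale reproductions: qualitative patterns
  and orders of magnitude, not asymptotic values, are the claim.
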