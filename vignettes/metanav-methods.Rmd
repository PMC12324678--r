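---
title: "Few-shot grid-world navigation: models and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot grid-world navigation: models and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metanav)
```

## The task

Every trial presents a wholly novel world: an 8x8 grid of uniquely
identified states inside a 10x10 wall ring, optionally cluttered with eight
obstacles placed one per interior row and one per interior column. A
navigator starts exactly four path-steps from a goal and moves by one of
two *action modalities*: clicking a cardinal **direction** (the behavioural
signature of a vector-based strategy) or clicking the identity of an
**adjacent state** (a transition-based strategy). Four conditions control
which modality is available: `both`, `directions_only`, `states_only`, and
`random_alternation`, where exactly one modality is available per step (the
direction modality with probability 0.75 in the open field and 0.50 in
cluttered worlds, matching pilot human direction-use rates). Each step
costs 50 points; the goal pays 1,000; trials start with 1,000 points, and a
memory probe awards 30/20/10/0 points at Manhattan error 0/1/2/>2.

Before navigating, a learner studies a bird's-eye map: 16 landmark
exposures spread over 2, 4, 8, or 16 unique landmarks (so fewer unique
landmarks are each seen more often), scheduled so no landmark repeats
consecutively and every landmark appears once per round. A free-form
variant (`day2`) relaxes the placement constraints: edge cells are allowed,
unique counts range over 2..16, and the 16 clicks spread unevenly.

## Simulated spatial memory

Agents replace the map-reading phase with a calibrated noise model over
coordinate estimates. Per trial the goal estimate is corrupted with
per-axis Gaussian noise of s.d. `s_goal ~ N(0.91, 0.44)`; landmark noise
follows the exposure law `s = m * log(n_exposures) + c` with per-agent
slope `m ~ N(-0.63, 0.34)` and intercept `c ~ N(1.90, 0.60)`. All s.d.
draws are floored at zero rather than redrawn — a negative s.d. is
undefined, and flooring moves the goal-noise mean by less than 0.005, the
smallest distortion among the available conventions. The log is the
natural log (the base is not dictated by the exposure law itself; it is a
`memory_noise_params()` knob). Estimates stay continuous — never rounded
or clipped to the lattice — and are frozen within a trial. States with no
memory item, including the wall/obstacle sentinel 65, read back as
all-zero coordinates with zero confidence.

## The observation contract

The agent sees a 48-slot vector per step, in fixed order: condition
one-hot (4); the eight obstacle (x, y) pairs sorted row-major (16, zeros
in the open field); state- and direction-availability flags (2); current,
four adjacent (N, S, W, E) and goal state identities as raw integers (6);
remembered (x, y) estimates for those six states (12); the noise s.d. of
each estimate as a confidence signal (6); and the last displacement
(dx, dy) (2). Identities are scalars, not one-hots — the slot budget
forces that reading. Coordinates use x = column, y = row, with row 0 at
the top; the paper-level sources never fix a convention, so one is chosen
and stated. Crucially, the agent's own position is *not* given: it must
be inferred by integrating displacements and recognising landmarks, which
is what makes the task a few-shot memory problem rather than plain
gradient descent.

## Agent and training

The policy/value network is an LSTM with 100 recurrent units feeding
separate two-layer (64-unit, tanh) heads; invalid actions are masked by
overwriting their logits with -1e8 at choice time, so a masked action's
softmax probability underflows to zero. Training is proximal policy
optimisation with the printed hyperparameters (learning rate 3e-4, value
coefficient 0.5, entropy coefficient 0.001, clip range 0.2, global
gradient-norm cap 0.5). Policy and entropy terms are computed over valid
actions only. Two published-equation readings needed a decision:

* **Sign convention.** The loss is written as a sum that *adds* the
  clipped surrogate, yet the surrogate is an objective. We minimise
  `-surrogate + c1 * value_error - c2 * entropy`, the standard convention
  that makes minimisation maximise the surrogate and the entropy bonus.
* **Advantage estimator.** None is printed; we use generalised advantage
  estimation with gamma = 0.99, lambda = 0.95 (the reference
  recurrent-PPO defaults), both configurable. Returns are
  `R_t = A_t + V_t`, and truncation at the 200-step cap is treated as
  non-terminal: the cut-off return is bootstrapped with the value of the
  post-step observation.

Rewards are the human point schedule divided by 1,000 (-0.05 per step,
+1 at the goal), which preserves the optimal policy while keeping value
targets near unit scale. Advantages are batch-normalised. The LSTM, its
backpropagation-through-time, and Adam are implemented directly in matrix
code; the loss path is verified against finite differences and an
independent scalar-loop oracle in the tests.

**Problem sizes.** The study-scale geometry — 128 parallel environments,
8,192 steps per update (1,048,576 environment steps per batch), 8,000
updates, 20 seeds — is retained behind `ppo_config(scale = "full")` but is
cluster-class work (~8.4e9 steps per seed). The package's own runs use a
desk-scale geometry chosen once as a workstation-sized training budget:
16 environments x 128 steps x 240 updates with 10 optimisation epochs per
batch (~0.5M environment steps), on the open-field `both` condition. That
budget reliably crosses the qualitative threshold we require of it —
greedy (argmax) evaluation beating the uniform-random-valid baseline on
median steps-to-goal — but it does *not* reproduce the study-scale
behavioural quantities (73.2% direction use; 65.8% conjunctive units),
which sit four orders of magnitude away in compute. Tests and the
analysis scripts therefore check desk-scale properties and
planted-ground-truth recoveries, not those headline percentages.

Evaluation is deterministic: the argmax of the masked logits, ties broken
toward the lowest action index. Early in training a deterministic policy
can loop between two states; the stochastic policy does not, which is why
training curves (sampled actions) improve before greedy evaluation does.

## Unit analyses

**Classification.** Units are typed on four fixed two-landmark
environments (landmarks at ((2,2),(5,5)), ((2,5),(5,2)), ((2,2),(5,2)),
((2,5),(5,5))). Per unit we average the cell state at each of the 64
locations per environment, smooth each 8x8 map with a Gaussian filter
(sigma = 0.7 cells, half-sample symmetric boundary, which conserves the
map mean exactly), and fit a two-factor ANOVA over the 256 pooled points:
quadrant (the four 4x4 blocks) by on-or-adjacent-to-landmark (the landmark
cell plus its 4-neighbours; the movement topology motivates excluding
diagonals). Labels follow the stated rule at alpha = 0.05 uncorrected:
only-quadrant means `spatial`, only-landmark means `landmark`, both main
effects and/or the interaction mean `conjunctive`, neither means `none`.
Two caveats are worth recording: smoothing correlates neighbouring cells,
so the ANOVA's independence assumption is generous and the false-positive
rate of each factor test exceeds its nominal level (for pure-noise units
the expected `none` rate is about 0.95^3 ~ 0.86 even *without* smoothing,
since three tests each fire at 5%); and environments are pooled as
replicates rather than modelled as a factor. Both follow the source
procedure as written.

**Modules.** Each unit's cell state is regressed on each of the eight
action logits; a unit's direction score is its mean simple-regression
R-squared over the four direction logits, likewise for state logits. The
top k per criterion form the `vector` and `transition` modules; the bottom
k on the maximum of both scores form the `unspecialized` control. The
methods text says k = 10 while a figure caption says 20; we default to 10
(the methods value) and keep k configurable. A unit in both top-k sets is
assigned to the criterion where it explains more variance and the loser
backfills from its next-ranked unit, ties toward the lower unit index.

**Lesions** zero the chosen units' cell and hidden states at every
timestep before any downstream use. The empty lesion is bit-identical to
the intact network; the full lesion leaves logits that depend only on head
biases, hence observation-independent within a step. Lesioned and intact
models are compared on identical trial seeds.

**Decoding.** Current and goal locations are decoded with closed-form
ridge regressions (penalty 0.5, unpenalised intercept — the same objective
as the reference implementation's `Ridge(alpha = 0.5)`), fit on a seeded
80% split and scored as mean held-out Euclidean error. Binary
landmark/goal adjacency is decoded with logistic regression after seeded
undersampling of the majority class. **Geometry** is a mean-centred,
unscaled PCA of a module's cell states, with the first three component
scores averaged per location under a condition split (before/after the
first landmark encounter, or landmark vs non-landmark).

## Sampling analytics

Accessibility is the mean over all 64 cells of the distance to the nearest
landmark; centrality is the mean distance from landmarks to the interior
centre (3.5, 3.5). Distances are Manhattan grid steps: that is the only
metric under which the uniform-placement chance level equals the printed
value of 4 (`chance_center_distance()` verifies this by exact
enumeration), and a Euclidean variant stays behind a flag. Metrics count
each unique landmark cell once by default — resampled cells do not weight
the metric — with a count-weighted toggle. The sampling PCA operates on
the subjects x 64 count matrix, column-centred and unscaled, with loadings
reshaped row-major to 8x8 for display.

## Synthetic generators

Every analysis consumes a generator with known ground truth:

* **Participants** follow a noisy goal-gradient policy — with probability
  `competence` the valid move minimising the estimated distance to the
  *remembered* goal, otherwise a softmax over negative estimated distances
  with temperature growing as competence falls — and an independent
  modality draw with destination-contingent state-response probabilities
  (goal, landmark, previously-visited, base, in that precedence). This is
  the simplest generative policy whose statistics reproduce the empirical
  regularities the behavioural analytics measure; it is a test harness,
  not a cognitive model. With zero noise and full competence it solves
  every open-field trial in exactly 4 steps.
* **Probe responses** add per-axis Gaussian noise, rounded to the nearest
  cell and clipped to the interior (probes are clicks on the lattice).
* **Sampling strategies** concentrate 16-click budgets near the centre,
  the corners, uniformly, or in a centre/corner mixture.
* **Planted units** compose quadrant means, landmark-adjacency bumps,
  multiplicative conjunctions, or pure noise, with optional linear wiring
  into synthetic action logits as module-identification ground truth.

What the generators deliberately do not emulate: within-trial learning,
response times, fatigue or block effects, and the correlation structure of
real human memory errors. Passing recovery tests therefore certifies the
analysis pipeline's correctness on data satisfying its assumptions, not
conclusions about human data.

## Numerical choices and degenerate inputs

Masking uses -1e8 (softmax underflow to exactly 0 in double precision
while keeping log-probabilities finite). Strict-variant exposure
allocation rejects unique counts that do not divide 16. Impossible start
placement triggers map regeneration, capped at 100 attempts. Unreachable
BFS queries return `Inf` rather than an error. Cells unvisited during
activation recording are imputed with the unit's grand mean before
smoothing (rare at the default trial counts). Degenerate-variance units
are labelled `none` with their p-values set to `NA`. The sampling PCA
refuses constant matrices. Blocked moves — reachable only when masking is
disabled — change nothing and cost nothing, matching the human task rule.
The day-2 human dataset contained a bug that could place starts on
landmarks; the generator does not reproduce it.

## Known limitations

* Desk-scale training shows qualitative learning, not the study-scale
  behavioural or representational quantities (see Problem sizes above).
* Mixed-effects and Bayesian model comparison are out of scope by design;
  the behavioural module exports tidy per-step/per-trial tables for
  external statistics tooling instead.
* The optional reader for the authors' archived human CSVs is not
  included; trajectory I/O uses the package's own documented JSON-lines
  schema.
* Whether the four state-action slots should be order-randomised per step
  (as the human display was) is undecidable from the integer-slot input
  specification; fixed N, S, W, E slots are the natural reading and carry
  the same information.
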