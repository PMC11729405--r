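---
title: "Mapping and stress-testing the reachable behaviors of gene-network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and stress-testing the reachable behaviors of gene-network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grnavigate` studies ODE gene-network models the way a behavioral
scientist studies an animal: it drives the model into as many distinct
"goal states" as possible with controlled interventions, then probes how
reliably each goal is re-attained under environmental perturbations. This
vignette documents the model, the procedures, the tunable parameters, the
numerical decisions, and what the synthetic fixtures do and do not show.

## Models and the rollout contract

Three model classes share one rollout contract (a uniform output grid of
`T/dt + 1` points; default `T = 2500` s, `dt = 0.1` s, hence 25,001 points
per trajectory):

* **Transcriptional gene circuit** `gene_circuit(W, B, tau)`, advanced with
  the exact discrete update
  `y_{t+1} = (dt/tau) sigmoid(W y + B) + (1 - dt/tau) y`.
  The update is a convex combination of the previous state and a sigmoid
  value, so states stay in (0,1) whenever the initial state does and
  `dt/tau <= 1` (enforced as a precondition). This explicit form is used
  deliberately instead of an adaptive solver: the discrete step *is* the
  model.
* **Generic ODE models** `ode_model(n, rate_fn, ...)`, integrated with
  `deSolve::lsoda` at absolute tolerance `1e-6`, relative tolerance
  `1e-12` and a 1000-step cap. Both tolerances are plain configuration
  values and are exposed as such (note the default relative tolerance is
  the tighter of the two). Integration restarts at every hook point so
  instantaneous perturbations and clamps are respected exactly.
* **Map models** `map_model(fn, n)`: the rollout is a constant trajectory
  at `fn(i)`. These are synthetic fixtures whose intervention-to-behavior
  mapping is known analytically; they exist to make exploration claims
  testable.

Two horizons appear in practice: `T = 2500` for analyses, and a longer
default time course (e.g. `T = 25000`) when deriving intervention bounds
from a model's unintervened dynamics. Both are ordinary `rollout_config()`
values; nothing in the package hard-codes either.

Hooks apply in a fixed, documented order after each step: state update,
then displacement events (noise kicks, pushes), then the wall constraint,
then clamps. Non-finite states *flag* a trajectory invalid rather than
raising — the curation layer needs to count failures, not crash on them.

## Spaces

An **intervention space** is a hyper-rectangle of either initial states
(dimension n; bounds built from the default trajectory as
`[min/r, r * max]` per node with `r = 20`) or joint circuit parameters
`(y0, W, B)` (dimension `n^2 + 2n`; order: initial states, `W`
column-major, `B`; `tau = 1`).

A **behavior space** encodes a trajectory into a descriptor:

* `endpoint` — the final state of a target node pair (the reached goal
  state), Euclidean distance;
* `fourier` — the unnormalized amplitude spectrum of one node over the
  settled half-window `[T/2, T]`, truncated to 256 bins, with mean
  absolute spectral difference as distance. The half-window excludes the
  transient; 256 bins keep the catalog distance cheap while retaining all
  of the low-frequency content where these circuits oscillate. Neither
  window nor truncation is canonical — they are this package's recorded
  choices.
* `oscillation` — the analytic `(A, omega, b)` triple on the same
  half-window: offset = mean, amplitude = half the peak-to-peak range, and
  the main frequency from the maximal non-DC DFT bin, refined to sub-bin
  precision by maximizing the windowed Fourier amplitude over a continuous
  frequency around the peak (plain bin argmax quantizes omega to
  `1/(M dt)` ≈ 8e-4 Hz, which is an 8–16% error at the low end of the
  frequencies of interest; the refinement brings recovery of synthetic
  cosines within 1%). Ties break toward the lower frequency; a constant
  signal reports omega = 0 by convention.

## Exploration

`run_random_search()` draws interventions uniformly — the screening
baseline. `run_imgep()` implements the simple curiosity-search variant:

1. bootstrap with `N_init` uniform interventions (default 10% of the
   budget — the bootstrap share is not canonical, only its existence);
2. then iterate: sample a goal uniformly in the bounding box of reached
   descriptors scaled by `box_scale = 1.3` about its center; select the
   valid record with the nearest descriptor; perturb its intervention with
   `Normal(0, step_frac * (high - low))`, `step_frac = 0.1`, clipped to the
   bounds; roll out, encode, append.

Three named RNG substreams (bootstrap, goal sampling, policy steps) derive
from the run seed, so an IMGEP with `N_init = N` is record-identical to
random search under a shared seed, and each component replays
independently. Degenerate goal boxes (a single reached point) are floored
at 1e-6 of the axis scale so the first goal-directed iteration is defined.
Invalid rollouts are stored but excluded from nearest-neighbor queries —
the policy must not chase numerical failures.

Catalogs are descriptor-only by default: every record is exactly
replayable from its stored intervention and configuration, and storing
thousands of 25,001-point trajectories is rarely worth it. Persistence is
a plain-text bundle (CSV records at full double precision, JSON metadata
and perturbation specs).

## Perturbations and robustness

Three trajectory-conditioned families, all scaled by the per-node extent
(max − min) of the *unperturbed* reference trajectory:

* **noise** — Gaussian kicks of sd `sigma_n * extent` every `p_n` seconds
  from t = 0 for an 80 s window (the window is a fixed convention here,
  configurable; no general rule exists for it);
* **push** — `n_p` instantaneous displacements of magnitude
  `m_p * extent` in uniformly random directions, at times uniform in
  `[0, settling time]`, where settling reuses the curation criterion
  (first time the trajectory is within 2% of its endpoint);
* **wall** — `n_w` segments of length `l_w * ||extent||`, centered at
  uniform fractions of the reference path length in the 2-D behavior
  plane, perpendicular to the local motion. Walls are hard constraints:
  a step whose behavior-plane segment crosses a wall is stopped at the
  crossing point and slid tangentially, with an epsilon nudge back to the
  pre-crossing side. The projection law is chosen for determinism and
  testability over repulsive force fields; it guarantees continuity (no
  teleportation) and never manufactures NaN.

The default grid holds 18 sub-families — six per family, replicated 3
times (P = 54 draws per goal). The printed parameter sextuples are read
magnitude-first for their first three entries and count-first for the
last three, since fractional event counts are meaningless; this keeps a
duplicated middle sub-family in each family, which is retained as printed.

A goal's **sensitivity** is the mean over valid perturbed rollouts of
`||z_p − z||` divided by the extent of the reference trajectory in the
behavior plane — "extent" here is the Euclidean norm of the per-axis
ranges (per-axis normalization is available as an alternative; the scalar
norm is the package's reading of an underspecified term). Invalid
perturbed rollouts are excluded from the mean and counted separately: a
NaN is a solver artifact, not an endpoint. Zero-extent references fall
back to absolute units with a flag. The pooled mean over all P
perturbations is the headline per-goal sensitivity; the
versatility-robustness curve uses the wall-family mean by default.

Representative goals for the battery are chosen by drawing 500 random
K-subsets (K = N/10 by default) and keeping the one with maximal
threshold coverage; subset scoring uses a coarser integration grid (512
cells/axis) than the reporting metric since only the argmax matters.

## Diversity metrics

`threshold_coverage()` rescales descriptors to the unit square with a
shared normalization box, then integrates the area of the union of
ε-disks (ε = 0.05) over the ε-padded square on a deterministic
2000×2000 grid, and divides by the padded-square area `(1 + 2ε)^2`.
Under this normalization four mutually disjoint attractors score exactly
`4πε²/(1+2ε)² ≈ 0.026` — the analytic bound used as a calibration point;
this is the only normalization under which that closed form holds, which
is why it was adopted. Disk area overhanging the unit square still counts
(it cannot leave the padded square). The grid integrator is cross-checked
in the tests against the closed-form two-disk lens formula and a
Monte-Carlo dart oracle. Threshold coverage is supported in 2-D only;
`binning_coverage()` (20 bins per dimension by default) serves
higher-dimensional spaces such as the `(A, omega, b)` oscillation space.

## Curation

`classify_trajectory()` applies three criteria to a target node: validity
(no NaN, no negative concentration anywhere), settledness (no time in the
last 100 s — t ≥ 2400 at the default horizon — deviating from the
endpoint by ≥ 2% of the net displacement, per-node scalar differences),
and periodicity (some non-DC bin of the unnormalized second-half DFT with
magnitude ≥ 40). The threshold 40 is meaningful only at the default
sampling — a 12,501-point window, where a pure sine of amplitude 0.1
peaks near 625 and tiny numerical ripples stay far below — so every
classification records its window length. Equality cases: the settledness
inequality is strict-`>=` against the limit, and the batch filter F1
fires at exactly 20% flagged (inclusive).

The system-level filters mirror the database-curation protocol on 50
rollouts from uniform initial states: F1 (≥ 20% invalid/unsettled/
periodic, on either behavior node), F2 (endpoint range < 0.1 on either
axis — both axes must span the minimum), F3 (endpoints occupy ≤ 4 bins of
a 20×20 binning over the endpoint bounding box). Random 3-node circuits
sampled at the package's own sampling law (nonzero `W ~ U[-30,30]`,
`B ~ U[-10,10]`, `tau ~ U[1,15]`) essentially never pass F3 — the
sigmoidal circuit family simply does not produce four-attractor endpoint
sets — and the acceptance suite verifies a ≤ 5% pass rate over 300
circuits with initial states drawn in `[0,1]^n`.

## Energy landscapes

`estimate_energy_landscape()` histograms all visited trajectory states in
the behavior plane on a G×G grid (G = 100 by default), adds a pseudocount
(0.5 per cell — both values are package choices, neither is canonical),
normalizes to a visit probability P and reports `U = −ln(P)`. All time
points weigh equally (full trajectories, no burn-in discard). The default
smoothing is interpolating (the gridded U is untouched); optional
smoothing fits cubic smoothing splines along rows then columns.
Attractors appear as local minima of U; the never-visited plateau is
excluded from minima detection.

## Oscillator-circuit engineering

The benchmark searches the 15-dimensional `(y0, W, B)` space of a 3-node
circuit (`tau = 1`, node 1 is the phenotype) for rollouts matching a
target wave `A cos(2π ω t) + b`, with targets drawn as `A ~ U(0.1, 0.5)`,
`b ~ U(A, 1−A)`, `ω ~ Beta(2, 8)` (Hz). The loss is
`L = Σ_t (y(t) − target(t))²` over the output grid. Four strategies share
one budget (5000 by default):

* **adam** — exact gradients of L through the unrolled discrete update,
  computed by forward-mode sensitivity propagation in C++ (n = 3 keeps the
  n×p tangent cheap). The configured moment coefficients are 0.02 and
  0.001 with lr = 1e-3 and eps = 1e-8, mapping the benchmark's stated
  hyperparameter names onto (β1, β2) as the only consistent reading;
  standard (0.9, 0.999) moments are available via a flag.
* **cmaes** — a minimal (μ/μ_w, λ) CMA-ES written for this package
  (fitness −L, box clipping, per-axis step scaling by the box extent,
  initial mean at the space center, initial σ = 0.25 of the normalized
  axis — initialization is unstated in the benchmark definition and
  recorded here).
* **random** — uniform draws.
* **imgep** — curiosity search over the Fourier behavior space; the loss
  plays no role during exploration.

`run_oscillator_benchmark()` counts sustained oscillators with the same
DFT criterion as curation (every counted circuit re-verifies when
re-simulated from its stored intervention), measures discovery diversity
in the `(A, ω, b)` space with 20-bins-per-dimension coverage over the
fixed box A ∈ [0,1], ω ∈ [0, 0.5], b ∈ [0,1], and finetunes the best
random/IMGEP discoveries with 100 adam steps behind an accept-if-better
guard (finetuning can therefore never worsen the reported loss). Each
benchmark run uses a single sampled target; pooling over targets is a
caller-side loop.

At the 5000 budget, curiosity search typically finds on the order of a
thousand sustained oscillators and random search on the order of a
hundred or fewer — an order-of-magnitude gap driven by the goal-directed
exploitation of discovered oscillatory regions of parameter space. The
exact counts are stochastic and the acceptance script recomputes them
from scratch at every run.

## Setpoint-reset design

`clamp_schedule()` describes a piecewise-constant stimuli intervention —
one node overwritten at every output step, switching levels every 10 s
for 100 s by default. `evaluate_reset()` scores a schedule as the mean
endpoint distance to a target setpoint over start states × battery draws;
`search_reset_intervention()` random-searches clamp-level sequences drawn
log-uniformly within `[0.1×, 10×]` of the start states' clamp-node level
("near the current steady states" quantified as one decade each way — a
package choice, configurable). Consequently the effective intervention on
a bistable toggle is to *suppress the dominant inhibitor* (clamp the
currently-high node low), not to force the low node high — candidates are
anchored to the level the node actually has.

## What the synthetic fixtures show — and what they do not

The test fixtures are constructed to make each claim falsifiable: a
zero-weight circuit isolates the recursion algebra; synthetic cosines
calibrate the DFT criteria; a 90%-redundant analytic map demonstrates the
IMGEP coverage advantage exactly where goal-directed exploration should
help; a two-node toggle provides genuine bistability for landscape and
reset claims. Passing these tests shows the machinery is correct and that
the qualitative phenomena (curiosity search out-covering random search on
redundant mappings; robustness heterogeneity across goals) emerge as
expected. It does not show that any particular *biological* pathway is
versatile or robust: real curated pathway models have richer kinetics,
stiffness, and conservation structure than random sigmoidal circuits, and
conclusions about them require running the same pipeline on those models
through the `ode_model` contract (e.g. via an external SBML-to-rate-
function adapter, which this package deliberately does not re-implement).

## Problem sizes used in the shipped analyses

The acceptance script runs the two 5000-rollout searches at the full
default horizon (25,001 steps each) — a few minutes on one CPU with the
compiled rollout core. The test suite exercises the same code paths at
reduced horizons (T = 100–500 s) where only the mechanics are under test,
and at full scale where the claim is scale-bound (the DFT threshold, the
5000-budget oscillator counts, the 300-circuit filter protocol).

## Known limitations

* Threshold coverage is 2-D only (by design; binning covers higher
  dimensions).
* Walls exist in the 2-D behavior plane, not the full state space.
* The adaptive-ODE path steps on the output grid when walls are active,
  trading solver efficiency for constraint fidelity.
* No stochastic (SSA) simulation, delay equations, or SBML event
  semantics.
* CMA-ES is a minimal implementation intended as a benchmark baseline,
  not a general-purpose optimizer.
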