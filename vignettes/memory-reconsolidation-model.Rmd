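---
title: "An attractor-network model of memory reconsolidation and extinction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An attractor-network model of memory reconsolidation and extinction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memrecon)
```

## The scientific problem

Amnestic drugs such as the protein-synthesis inhibitor anisomycin,
injected after an animal is reexposed to a conditioning context, can
produce two opposite outcomes: they erase the fear memory
(*reconsolidation blockade*) after short-to-intermediate reexposure, and
they *preserve* it (extinction blockade) after long reexposure.
`memrecon` implements a network-level account of this dichotomy: both
phenomena emerge from a single pair of plasticity mechanisms operating
on an autoassociative (hippocampus-like) attractor network, with the
outcome determined by the similarity between the animal's current
contextual representation and the stored attractor.

## The model

**Dynamics.** `N = 100` rate neurons with activations
$u_i \in [0, 1]$ evolve by

$$\tau \frac{du_i}{dt} = -u_i +
  \tfrac{1}{2}\left(1 + \tanh\big(\textstyle\sum_j w_{ij} u_j + I_i\big)\right)$$

with time constant $\tau = 1$ and cue currents
$I_i \in [-5, 5]$.  The 0/1 activation scheme (rather than the
classical $\pm 1$ one) avoids symmetric-connectivity assumptions,
strengthening between silent neurons, and mirror attractors.  The
network is relaxed to steady state by forward Euler
(`relax()`, implemented in C++) with `dt = 0.1` $\tau$, a steady-state
tolerance of $10^{-6}$ on $\max_i |du_i/dt|$, and a time cap of
$100\,\tau$.  Because `dt < tau`, each Euler update is a convex
combination of the state and a value in $(0,1)$, so boundedness holds
exactly at every step.  Halving `dt` moves relaxed states by less than
$10\times$ the tolerance (tested), which guards the integrator choice.

**Memory patterns.** Three binary patterns over fixed index blocks
(`build_patterns()`): an *unrelated* memory, the *shock* memory and the
*non-shock* (extinction) memory, each with 14 active neurons.  The shock
and non-shock patterns share 4 *context* neurons (28.6% overlap); the
unrelated pattern is disjoint.  The layout is deterministic, so
replicate variability comes only from random initial conditions, drawn
uniformly from $[0, 0.1]$ per neuron.

**Plasticity.** After every learning or reexposure session the weight
matrix is updated from the steady state $u$ reached under that session's
cue:

$$w \leftarrow \mathrm{clip}\big(w + \mathrm{HLP} + \mathrm{MID},
  \pm s_0\big), \qquad
  \mathrm{HLP}_{ji} = S\, u_i (2 u_j - 1), \qquad
  \mathrm{MID}_{ji} = D\, u_i m_j,$$

where $m = \hat{I} - u$ is the mismatch between the normalized cue
$\hat I = (I + I_{max}) / (2 I_{max})$ and the attained state, and
$s_0 = 1$ truncates weights symmetrically.  HLP (scaled by the
synthesis factor $S = 0.8$) is Hebbian: $+S$ between coactive neurons,
$-S$ from active to silent neurons, nothing from silent neurons.  MID
(scaled by the degradation factor $D = 1.25$) degrades exactly the
synapses responsible for cue/attractor disagreement: $+D$ onto units
the cue activates but the attractor suppresses (AS), $-D$ onto units
the cue suppresses but the attractor keeps active (SA).  The two
closed forms are the minimal continuous interpolations of the discrete
case tables; the test suite checks them against a brute-force
enumeration of all binary cases rather than trusting the algebra.
Drugs are per-session scalar overrides: anisomycin $S = 0$, plasticity
enhancers $S = 0.95$, degradation blockade $D = 0$.

**Reexposure cues.** A nonreinforced reexposure of duration
$t \in [0, 10]$ presents
$I(t) = (1 - f(t))\, c_{shock} + f(t)\, c_{nonshock}$ with the logistic
$f(t) = 1/(1 + e^{-(t - 5)})$ (midpoint 5, slope 1 — any monotone map
onto $[0,1]$ is qualitatively equivalent; both are configuration knobs
in `model_params()`).  Context neurons are driven at $+5$ for every
$t$; neurons unique to one memory move from $+5$ to $-5$ (or back) as
$t$ grows.

**Behavioral readout.** A retrieval test presents a weak current
(0.1) on the 4 context neurons, relaxes the network from a fresh random
state, and classifies the attractor by Pearson correlation against the
stored patterns (threshold $r > 0.7$; a constant state has no defined
correlation and counts as no retrieval).  Retrieval of the shock
pattern yields 90% freezing, anything else 10%.  Protocols repeat the
whole session sequence for (by default) 100 replicates and report mean
± SEM.

## Inter-session decay

The decay factor $\gamma = 0.15$ is applied as a discrete event
$w \leftarrow (1 - \gamma) w$, once, after training and before the
(first) reexposure session; multi-session extinction protocols apply it
only before the first reexposure, so single- and multi-session
protocols start their reexposure phase from the same weights.  A
continuous (per-session) application was considered and rejected: the
one-event placement is what makes the competition between stored-
attractor completion (context weights $\times$ 4 neurons) and the
increasingly non-shock-like cue cross over near $t \approx 8$, the
extinction onset the simulations reproduce.

## What the model does, mechanistically

* **Initial learning** clamps the network to the cued pattern, so the
  mismatch vanishes and only HLP acts.  With $S = 0$ nothing is stored.
* **Short reexposure** ($t \lesssim 4$) retrieves the shock attractor
  with little mismatch: anisomycin has almost nothing to block
  (*simple retrieval*).
* **Intermediate reexposure** ($t \approx 5$–$7$) still retrieves the
  shock attractor, but the mismatch on the cue-suppressed shock neurons
  is large: MID degrades the attractor and HLP normally rebuilds it.
  With $S = 0$ the degradation is unopposed — reconsolidation blockade.
  With $D = 0$ the degradation never happens, which is why degradation
  blockade rescues the anisomycin deficit: the $S=0, D=0$ session
  leaves the weights exactly untouched, and freezing returns to its
  post-training level.
* **Long reexposure** ($t \gtrsim 8$) prevents retrieval of the shock
  attractor altogether (the cue clamps its unique neurons down faster
  than pattern completion can rescue them); the non-shock pattern is
  written as a new attractor.  Anisomycin now blocks that new learning
  and thereby *preserves* fear.
* **Overlap.** Rebuilding the patterns with more shared neurons
  strengthens pattern completion during reexposure: above ~30% overlap
  (5+ of 14 neurons) the shock attractor is reinstated at every
  duration and extinction never occurs.

## Graded retrieval and the freezing scale

With the weak 0.1 test cue, retrieval is only *biased* — not forced —
toward the cued pattern: when the shock and unrelated memories have
equal weights, the shock pattern wins in roughly 55–60% of
initializations (mean freezing ≈ 55), and freezing percentages move
smoothly with the weight difference between competing attractors.  This
is a deliberate property of the readout (the model's freezing scale is
linear in retrieval probability), but it means "high" freezing after
plain training is ≈ 55–90 depending on how recently the shock memory
was reinforced, not a fixed ceiling.  One acceptance comparison is
sensitive to this: at $t = 8$ the control group has already crossed the
extinction midpoint (the saddle-node of the shock attractor sits at
$t \approx 7.8$ under the default sigmoid), so the plasticity-enhancer
contrast at exactly $t = 8$, while having the correct sign (13 vs 0
shock retrievals per 100 in our runs), cannot reach a 30-point freezing
gap.  The corresponding check is left failing rather than re-tuned,
since moving the sigmoid midpoint to enlarge it would be calibration
after the fact.

## Numerical choices

* **Integrator**: explicit Euler; smooth contraction-like dynamics at
  `dt` $\ll \tau$; consistency under step halving is asserted in tests.
* **Convergence**: $\max_i |du_i/dt| < 10^{-6}$; all protocol
  relaxations meet it before the $100\,\tau$ cap.
* **Self-connections**: the diagonal is re-zeroed after every update;
  autapses would let a neuron bootstrap itself independently of the
  stored pattern structure.
* **Ties**: attractor classification breaks correlation ties by lowest
  pattern id; in practice ties occur only for identical patterns
  (100% overlap sweeps), where the shock label is the conservative
  choice.
* **Energy bookkeeping**: the landscape energy is the quadratic
  Hopfield form $E = -\tfrac12 u^\top W u$ (optionally with the cue
  term $-I^\top u$).  Because the learned weights are asymmetric (the
  $-S$ active-to-silent entries have no mirror image), $E$ is not a
  strict Lyapunov function at sub-$\tau$ resolution: during the first
  half time-constant of a relaxation, while the whole network drifts
  off the random initial state, $E$ can transiently rise by order 1.
  Sampled at the model's natural unit-time resolution ($\tau$), and
  per step beyond the first $\tau$, energy is non-increasing along
  every protocol relaxation we test.
* **Landscape sampling**: half uniform-random binary states with 14
  active neurons (covers ridges), half relaxed states from random
  initializations (covers basin interiors); 50×50 grid, 20-nearest-
  neighbor smoothing; cells containing no sample are flagged by
  `n_in_cell = 0`, not treated as zero energy.

## Design decisions on open points

* **Parameter container**: the two parameter families (dynamics and
  plasticity) are bundled into one validated `model_params()` list —
  protocols override individual fields per session, and a single
  container keeps preset files and sweeps flat and explicit.
* **The unrelated-context session** (`sess_train_unrelated()`) trains a
  *novel* pattern on a fresh block of neurons, modeling exposure to a
  different context.  Re-training the already-stored unrelated memory
  would saturate its weights at $s_0$ and make it dominate every later
  retrieval test, which contradicts the phenomenon being modeled (no
  effect of the drug without reexposure to the learning context).  A
  side effect of the graded readout is that the *vehicle* arm of this
  protocol stores a third competing attractor and its freezing dips;
  the drug contrast — anisomycin leaves the shock memory exactly as it
  was — is unaffected.
* **Test-cue neurons in overlap sweeps**: when the shared set is not
  exactly 4 neurons, the 4-neuron test cue picks shared neurons first
  and then shock-unique neurons, so it always probes the shock
  context.
* **Capacity cues**: the storage-capacity protocol cues
  `cue_size` randomly chosen active neurons of the target pattern at
  full training strength.  The weak 0.1 current is a *behavioral-test*
  convention; at capacity scale it fails for reasons unrelated to
  storage interference and would not reproduce reliable 3-pattern
  retrieval at `N = 100`, which the behavioral protocols themselves
  presuppose.
* **Mixed-activation plasticity**: the continuous HLP/MID forms let
  partially active units (common near the extinction threshold)
  produce proportionally scaled updates; the discrete case tables only
  constrain the binary corners.

## Problem sizes and replication

Behavioral protocols use `N = 100` neurons and 100 replicates per
condition (matching the modeled experiments); the bundled duration
sweep covers `t = 0..10` and the overlap sweep `k = 0..14` shared
neurons × `t = 0..10`, both at 100 replicates per cell.  Capacity
curves in the tests are computed at reduced scale (sizes 100–200,
60 trials) to keep the suite fast; `capacity_curve()` defaults
reproduce the larger sweep (sizes up to 300, 200 trials) in under a
minute each.

## What the simulations do and do not show

All inputs are generated internally — patterns, cues and protocols are
the study conditions themselves, not fits to recorded data.  Passing
tests therefore show that the *mechanism* (attractor dynamics + two
opposing plasticity terms + duration-dependent cue mixing) reproduces
the qualitative pharmacobehavioral phenomenology: they say nothing
about biological parameter values, about within-session dynamics of
the animal's percept (the cue mix is an end-of-session summary), or
about which molecular cascades implement the degradation term.  The
two-region (CA3–CA1) mismatch-detection variant and spike-based
plasticity are out of scope.

## A worked run

```{r example, eval = FALSE}
library(memrecon)

# Reconsolidation blockade: anisomycin in an intermediate reexposure
run_experiment("fig3c", n_replicates = 100, seed = 11)

# Duration-response summary and the extinction onset
sw <- sweep_duration(0:10, n_replicates = 100, seed = 1)
extinction_onset(sw)  # 8 with the defaults

# Energy landscape after learning the unrelated and shock memories
ps <- build_patterns()
pars <- model_params()
set.seed(1)
w <- zero_weights(100)
for (id in 1:2) w <- run_session(w, sess_train(id), ps, pars)$w
plot(energy_landscape(w, ps))
```
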