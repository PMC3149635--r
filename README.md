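# memrecon

An attractor-network simulator of memory **reconsolidation** and
**extinction** in contextual fear conditioning.

Post-retrieval injection of amnestic drugs (e.g. the protein-synthesis
inhibitor anisomycin) can either erase a fear memory or preserve it,
depending on how long the animal is reexposed to the conditioning
context. `memrecon` implements a network model in which both outcomes
— and their pharmacology — emerge from one pair of plasticity
mechanisms acting on a Hopfield-style autoassociative network. It is
aimed at computational neuroscientists and at experimentalists who want
to explore how reexposure duration, training strength, pattern overlap
and drug conditions interact.

## The model in brief

`N = 100` rate neurons with activations `u_i ∈ [0, 1]` follow

```
tau du_i/dt = -u_i + 1/2 (1 + tanh( Σ_j w_ij u_j + I_i ))
```

Memories are binary patterns (14 active neurons; the shock and
non-shock memories share 4 context neurons) stored by cue-clamped
learning sessions. After every session the weights update from the
steady state `u` reached under the session cue `I`:

```
w ← clip(w + HLP + MID, ±s0)
HLP_ji = S · u_i (2 u_j − 1)        # Hebbian term, synthesis factor S
MID_ji = D · u_i m_j,  m = Î − u    # mismatch-induced degradation, factor D
```

with `Î` the cue normalized to `[0, 1]`. A nonreinforced reexposure of
duration `t ∈ [0, 10]` presents the sigmoid mixture
`(1 − f(t))·cue_shock + f(t)·cue_nonshock`, `f(t) = 1/(1+e^−(t−5))`.
Retrieval tests cue the context weakly (current 0.1), classify the
attractor by correlation (`r > 0.7`), and map shock-pattern retrieval
to 90% freezing, anything else to 10%. Drugs are per-session scalar
overrides: anisomycin `S = 0`, enhancer `S = 0.95`, degradation
blockade `D = 0`. Defaults: `tau = 1`, `S = 0.8`, `D = 1.25`,
`gamma = 0.15` (one inter-session decay event), `s0 = 1`.

## Worked example

Anisomycin during an intermediate-duration reexposure (t = 6) blocks
reconsolidation; the same drug during a long reexposure (t = 10) blocks
extinction instead:

```r
library(memrecon)
run_experiment("fig3c", n_replicates = 100, seed = 11)
#> protocol  condition   session_label  mean_freezing sem_freezing ...
#>    fig3c    vehicle    post-training          54.8          4.0
#>    fig3c    vehicle  post-reexposure          88.4          1.1
#>    fig3c anisomycin    post-training          54.8          4.0
#>    fig3c anisomycin  post-reexposure          10.0          0.0
```

After training, the weak context cue retrieves the shock attractor in a
(graded) majority of replicates, giving 54.8% mean freezing. A vehicle
reexposure reinforces the memory (88.4%), while anisomycin (`S = 0`)
leaves mismatch-induced degradation unopposed and erases it (10.0%,
the baseline: no replicate retrieves the shock pattern). With
`run_experiment("fig3d", ...)` (t = 10) the ordering reverses: vehicle
extinguishes (10.0%) while anisomycin preserves fear (52.4%).

The duration-response summary and its extinction onset:

```r
sw <- sweep_duration(0:10, n_replicates = 100, seed = 1)
extinction_onset(sw)
#> [1] 8
```

Mean freezing stays at 90 through t = 5, falls to 82.8 at t = 7 and to
18.0 at t = 8 — controls first extinguish at t = 8. Other entry
points: `run_test()` (retrieval statistics of a fixed network),
`sweep_overlap()` / `sweep_strength()` / `sweep_reexposure_factor()`
(regime maps), `energy_landscape()` + `plot()` (attractor basins on
the 2-D discriminant plane), `capacity_curve()` (storage capacity vs.
network size and sparseness), and `list_presets()` for the bundled
protocol catalog. A command-line driver wraps these:

```sh
Rscript scripts/memrecon.R run fig6a --seed 1 --out results/fig6a
Rscript scripts/memrecon.R sweep duration --seed 1 --out results/sweep
```

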