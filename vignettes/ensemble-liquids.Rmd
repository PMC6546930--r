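---
title: "Ensemble liquid state machines: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble liquid state machines: model, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidens)
```

# The model

A liquid state machine (LSM) projects an input spike stream through a fixed,
randomly wired recurrent pool of spiking neurons — the *liquid* — and trains
only a linear readout on the liquid's transient states. This package studies
the *ensemble* variant: a fixed neuron budget $N_{tot}$ is divided into
$N_{ens}$ smaller, mutually unconnected liquids that all receive the same
input, and their states are concatenated for the readout (so the readout's
parameter count is identical to the single-liquid baseline).

## Liquid neurons

Both populations (excitatory and inhibitory, held at a 4:1 ratio as observed
in auditory cortex) are conductance-based leaky integrate-and-fire neurons:

$$\tau \frac{dV}{dt} = (E_{rest} - V) + g_e (E_{exc} - V) + g_i (E_{inh} - V),$$

with dimensionless synaptic conductances that jump by the synaptic weight on
each presynaptic spike ($\Delta g_e = W S(t)$) and decay exponentially,
$\tau_g \dot g = -g$. A neuron whose membrane reaches its population
threshold at the end of a step spikes, resets to its rest potential, and is
refractory for $t_{refrac}$.

Parameters and their provenance:

| parameter | E | I | units | status |
|---|---|---|---|---|
| threshold | -52 | -40 | mV | stated |
| rest / reset | -65 | -60 | mV | stated (reset = rest) |
| conductance decay $\tau_{g}$ | 1 | 2 | ms | stated |
| membrane $\tau$ | 100 | 10 | ms | **assumption** (standard conductance-LIF values, Diehl & Cook) |
| reversal $E_{exc}$ / $E_{inh}$ | 0 / -100 | mV | | **assumption** (same formulation) |
| refractory | 5 | 2 | ms | **assumption** (same formulation) |

Connection masks are Bernoulli per edge at the per-pathway percentages
(image tasks: IN→E 10, E→E 40, E→I 40, I→E 50, I→I 0; speech presets differ
only in IN→E), weights are uniform(0, 1) on the mask support, inhibitory
weights are positive magnitudes acting through $E_{inh}$. Self-connections
are excluded in the square pathways — a package choice that avoids
degenerate self-excitation loops.

## Numerical scheme

The simulator is clock-driven at `dt = 0.5` ms (the reference encoder step,
adopted globally). Per step, in order: deliver input and recurrent spikes
*from the previous step*, decay conductances by the exact exponential
factor, integrate membranes by the exact exponential update with
conductances frozen within the step,

$$V \leftarrow V_\infty + (V - V_\infty)\,
  e^{-dt\,(1+g_e+g_i)/\tau},\qquad
  V_\infty = \frac{E_{rest} + g_e E_{exc} + g_i E_{inh}}{1+g_e+g_i},$$

then threshold and reset. The exponential updates are unconditionally stable
at this step size and bitwise reproducible. At most one spike per neuron per
step is allowed; at 0.5 ms this is also the physical refractory floor. Spikes fired during step $k$ are stamped $k\,dt$ and take
effect in step $k+1$; a neuron that fires at $t$ integrates again only at
step ends strictly beyond $t + t_{refrac}$, making the minimum inter-spike
interval $t_{refrac} + dt$.

Two engines implement the identical arithmetic in the identical order: a
compiled loop (default) and a pure-R loop composed from the exported
per-step operations. The test suite holds them bitwise equal, and holds both
equal to a third, naive scalar reference on small liquids.

## Encoders

Images (intensities 0–255) map pixel $i$ to a Poisson train of rate
$r_i = (I_i/255)\, r_{max}$, realized as per-step Bernoulli draws with
probability $r_i\,dt$; the default $r_{max} = 63.75$ Hz is the reference
white-pixel rate, and stimuli last 300 ms. Channel-intensity matrices
(cochleagram-like, 39 channels) are used directly as per-step firing
probabilities. The cochlear front-end itself is out of scope; the synthetic
generator fabricates class-structured channel matrices instead.

## Kernel-quality metrics

* **Filtered state**: each neuron's spike train through an exponential
  filter with a 30 ms time constant, evaluated at a query time.
* **Pairwise separation** $SP_{pw}$: mean Euclidean distance between two
  filtered state trajectories over a uniform grid of 20 sample times
  (the grid density is a package choice).
* **Separation / generalization rank**: the numerical rank of the matrix of
  filtered states at $t_0 = T$, columns being responses to $m$ distinct
  inputs (higher = better separation) or to jittered replicas of a few base
  inputs (lower = better generalization). Rank counts singular values above
  $10^{-6} \sigma_{max}$: states from finite spike counts are noisy and an
  absolute-zero cutoff would always return full rank.
* **Scatter statistics**: within-class scatter $S_w$ (prior-weighted sample
  covariances; the $n-1$ denominator is a package convention), between-class scatter $S_b$
  (prior-weighted outer products of mean deviations), priors are empirical
  class frequencies.
* **Discriminant ratio** $DR = tr(S_b)/tr(S_w)$, the singularity-proof
  surrogate for the Fisher ratio $tr(S_w^{-1} S_b)$; `fisher_ratio()`
  raises an error on ill-conditioned $S_w$ rather than regularizing
  silently, because the trace ratio exists precisely for that regime.

Input spike-train distances use the Gaussian kernel
$e^{-(t/\tau_{in})^2}$ with $\tau_{in} = 5$ ms. The continuous norm is
discretized on a 0.5 ms grid and scaled by $\sqrt{grid\_dt}$ so the value is
stable under grid refinement; the tests pin the discretization to within 1%
of a 10x finer grid. Jitter for generalization experiments is Gaussian with a 4 ms
default standard deviation (a package default, configurable).

## Readouts

The liquid state vector is the per-neuron excitatory spike count over the
stimulus window, divided by the maximum count in the sample — one of
several reasonable normalizations; a rate-ceiling alternative is available
via `normalize = "rate"`. The readout is one linear layer with
softmax output trained by mini-batch SGD on cross-entropy, chosen because
cross-entropy accepts the non-one-hot *inhibitory label* targets (uniform rows $1/L$)
natively. All argmax decisions break ties toward the lowest index,
deterministically.

Two multi-liquid configurations exist: **MLSR** (one shared readout on the
concatenated state) and **MLMR** (one readout per liquid, fused by the
maximum over all local scores; majority vote is available since both fusions
are described). MLMR training divides the training space randomly (RD) or
by clusters (CD); CD adds `x_f` = 10% of each foreign cluster with uniform
targets so local readouts stay quiet on clusters they were not trained for.
At four clusters this makes foreign instances $30/130 \approx 23\%$ of each
local training set, $100/13 \approx 7.7\%$ per constituent set.

# The synthetic world

No external corpora are used; generators fabricate each input class:

* **Spike-pair suite** — pairs $(u, v)$ of 39-channel, 40 Hz Poisson trains
  over 300 ms; $v$ re-draws a fraction of $u$'s spike times, the fraction
  ramping 0→1 across the suite so measured distances span a range. The
  fraction perturbs spike *timing* within channels (per-channel counts are
  preserved), giving controlled, graded inter-train distances.
* **Clustered images** — 16x16 soft-edged oriented-bar glyphs, one
  orientation per class, with per-image pose jitter; four clusters per
  image: original, rotated (±15°), shifted (±2 px), noisy (σ = 20 intensity
  units, clipped). The transform magnitudes are the package defaults chosen
  to make clusters distinct but classes recoverable. For the acceptance
  experiments the set uses **10 classes** — the class count of the digit
  tasks the image experiments emulate.
* **Channel signals** — per-class smooth cosine-ridge templates over
  39 channels, scaled into $[0, 0.1]$ per-step probability, plus clipped
  Gaussian noise.

What a green trend test establishes is therefore limited: the generators
emulate the *structure* (classes, clusters, controlled distances) of the
image/speech corpora, not their content, dimensionality (256 pixels vs 784;
~200 samples vs 240,000), or difficulty. Desk-scale liquids use
$N_{tot} = 135$ for kernel-quality runs (a conventional size for such
studies) and $N_{tot} = 200$ for image tasks (full-scale tasks use
500–2000 neurons).

## Operating point

The image-task input connectivity is set to $P_{IN\to E} = 30$ rather than
the tabulated 10: the tabulated value belongs to 784-pixel inputs, and input
connectivity has to be re-tuned per task and input dimensionality — the
optimum rises as the number of input lines falls. With 256 input lines at 30%,
the mean excitatory conductance drive lands in the same regime as the
tabulated setting does at 784 lines — a few Hz of liquid activity, neither
over-stratified (silent) nor pathologically synchronous. This was fixed from
the mean-conductance calculation before the trend experiments were run.

# Design choices

* **Sub-seeds**: every internal RNG stream is derived from the user seed by
  a fixed counter scheme (`derive_seed`), so ensembles, trials and encoders
  are independently reproducible; liquid $k$ of an ensemble uses counter
  $k-1$, making a one-liquid ensemble bit-identical to the single liquid.
* **Budget remainders**: when $N_{tot}$ is not divisible by $N_{ens}$, the
  remainder neurons go to the earliest liquids (deterministic, size spread
  of at most one); training-set remainders in RD division likewise.
* **Input binning**: an input spike during step $k$ (times in
  $((k-1)dt, k\,dt]$; time 0 counts as before the run) is delivered at the
  start of step $k+1$, the same one-step latency recurrent spikes have.
* **Saturation point** of a DR curve: defined operationally as the first
  ensemble size after which the remaining gain is below 5% of the total
  rise, an operational stand-in for reading the optimum off a curve.
* **Unimodality** of an accuracy curve: a peak with non-decreasing means
  before and non-increasing means after; a boundary peak qualifies.
* **Train/test split**: seeded, stratified 60/40 for synthetic tasks (the
  real corpora's fixed splits are out of scope).
* **Jitter clipping**: jittered spike times clip to the window rather than
  wrap or drop, prioritizing count preservation.

# Known limitations

* The trend experiments keep the percentage connectivities *fixed* across
  ensemble sizes. Under that convention a liquid of $N_{tot}/N_{ens}$
  neurons has $1/N_{ens}$ of the recurrent in-degree, so ensemble members
  run ~2–3x quieter than the single-liquid baseline, and the
  pairwise-separation and rank curves flatten or invert rather than rise
  with $N_{ens}$. Re-tuning $P_{IN\to E}$ per configuration (bisection to
  the baseline firing rate) restores the activity level but not a rising
  separation curve; recovering it appears to require re-tuning *all*
  pathway percentages per liquid size, for which no published values
  exist. The scale-invariant discriminant ratio and the readout accuracies
  are robust to the activity drop; they are the quantities the acceptance
  checks assert directionally, and the separation/rank directions are
  reported by the tests but fail in this fixed-connectivity world.
* Readout training is plain SGD with a fixed learning rate; no scheduling,
  regularization, or early stopping.
* The simulator forbids multiple spikes per neuron per step; at 0.5 ms this
  matters only for unphysiological drive.
* Event-driven simulation, synaptic plasticity, multi-compartment neurons,
  and parallel execution are out of scope; parallelism claims are analyzed
  via connection counts only.

# Reproducing the experiment tables

```{r, eval = FALSE}
cfg <- experiment_config(n_tot = 135, n_ens = c(1, 2, 4, 8, 10),
                         seeds = 1:10)
sp <- run_sp_experiment(cfg)

img_cfg <- experiment_config(
  n_tot = 200, n_ens = c(1, 2, 4, 5, 8, 10), seeds = 1:5,
  connectivity = connectivity_spec(p_in_e = 30),
  image_data = list(n_classes = 10, per_cell = 5, size = 16))
dr <- run_dr_sweep(img_cfg)
attr(dr, "saturation")
```

Every result table embeds a configuration fingerprint; rerunning with the
same configuration reproduces the table exactly. The same drivers are
exposed on the command line via `inst/cli/liquidens`
(`sp-run`, `dr-sweep`, `acc-sweep`, `gen-data`), taking `--config` (JSON),
`--seed`, `--out`, and `--n-ens`.
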