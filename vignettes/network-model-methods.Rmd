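---
title: "From neuron skeletons to a spiking brain model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From neuron skeletons to a spiking brain model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices, and numerical
decisions behind `flybrainsim`. The package turns single-neuron
skeleton morphologies (SWC files) into a conductance-based spiking
network model of a whole insect brain sample and analyses its
structure and dynamics. Every stage is usable on its own; the
synthetic generators make the whole pipeline testable without any
external data.

## Units

Lengths are in um, areas um^2, time ms, potentials mV, capacitance
pF, conductance nS, currents pA. The specific membrane capacitance
0.8 uF/cm^2 equals 0.008 pF/um^2 in these units.

## Polarity classification

Skeletons carry no axon/dendrite annotation, so each arbor must be
classified from its shape. Eleven morphometric features (path lengths
to the soma, branch orders, branch counts and angles, segment-length
statistics, convex-hull and Voronoi volumes) feed a linear classifier
whose shipped weights correlate positively with axonal identity for
features such as path length to soma (+0.599) and negatively for
features such as mean branch order (-0.413): axons in these brains
tend to be long, distal and sparsely branched, dendrites compact and
bushy.

Concrete feature semantics (the literature leaves room for variants):
branch order of a node is the number of branch points between it and
the soma; path lengths are geodesic along the skeleton; terminal
statistics average over a domain's terminals, `mean_path_length` over
all its nodes; the branch angle is the angle between the two daughter
directions at a branch point; and the mean Voronoi-cell volume of the
terminals clipped to the domain's convex hull equals the hull volume
divided by the terminal count, because the cells tile the hull.
Statistics over empty sets (no branch points, say) are defined as 0
rather than NaN so that single-terminal domains classify cleanly.

Arbor *domains* are the classification unit. Each primary neurite
(child subtree of the soma) starts one domain; a domain is split
recursively at a branch point when its sibling subtrees' terminal
centroids are further apart than a gap threshold (um). The
dimensionless `granularity` knob maps to that threshold as
`gap_scale / granularity`, so smaller granularity values merge
domains (the documented default 0.001 leaves typical bipolar neurons
with exactly their two primary domains) and the domain count is
non-increasing in the gap threshold. This is a deliberately simple
stand-in for more elaborate domain-separation schemes; precomputed
domain labels can be injected instead.

The training-time feature standardization behind the published
weights is unavailable, so the default classifier ships with identity
scaling and its scores are meaningful only up to monotone ordering.
`classify_polarity_batch()` therefore z-scores features across the
dataset at hand before applying the weights — the recommended default
— and a fitted `center`/`scale` can be supplied for calibrated use.
Ties at a score of exactly zero go to "dendrite": dendritic terminals
outnumber axonal ones in typical arbors, so the conservative tie
minimizes expected terminal error.

## Connection inference

A *contact point* is a pair (axonal segment of neuron i, dendritic
segment of neuron k) whose minimum Euclidean distance is within the
distance criterion (default 13 um). Segment-to-segment distance uses
the closed-form clamped formulation rather than node-to-node
distances, which would undercount sparse tracings. Counting is per
segment pair by default; a branch-pair aggregation (each axonal
branch x dendritic branch pair counts once) is available because the
field's descriptions are ambiguous between the two.

Neuron i is connected to neuron k when `N_ik / sum_j N_ji > R`, i.e.
the contact count is measured relative to the *input* contact total
of the presynaptic neuron. The output total may look more natural but
caps the number of downstream partners at `floor(1/R)`; input and
output totals are roughly proportional across neurons, which makes
the input total a serviceable denominator without that artifact.
Neurons with zero input contacts have an undefined ratio: they emit
no edges and a warning is raised, since the proportionality argument
fails exactly there. Two documented presets exist for `R` (0.01 and
0.001, both appearing in the source literature); both are plain
configuration values. Duplicate directed pairs arising from several
domain pairings are summed before thresholding.

`roc_scan()` tunes the two criteria against a reference adjacency by
TPR/FPR over ordered neuron pairs. The default selection rule is
"maximize TPR subject to FPR <= 0.06", with Youden's J as an
alternative, because the literature's "high true positive rate with a
reasonably low false positive rate" is not a formula. Note that edge
sets are provably monotone in `R` (shrinking `R` never removes an
edge) but *not* in the distance criterion: enlarging the distance
grows numerators and denominators together, so individual edges can
disappear. Only the `R` monotonicity is asserted by the test suite.

## Membrane parameters

The LIF membrane area is estimated from total skeleton length `l` as
`A = (l * 2 * pi * 0.147) * 2.38 + 5340` um^2 — a cylinder of radius
0.147 um with an empirical scale and offset calibrated against
measured neurons — giving `C_m = 0.008 * A` pF and `g_L = C_m / 16 ms`.
All neurons share V_resting -70 mV, V_threshold -45 mV, V_reset
-55 mV, tau_m 16 ms, and a 2.0 ms refractory period; size enters only
through C_m and g_L.

## Synapse model and scaling

Transmitter classes come from the driver prefix of the neuron name
(`Cha*` cholinergic, `VGlut*` glutamatergic, `Gad*` GABAergic,
anything else modulatory "other"). Only the three fast classes emit
synapses; "other" neurons stay in the model when they receive input
but contribute no conductance. Isolated neurons are dropped.

Per-synapse conductance scales are `B * k * N` with the contact count
`N`, a global excitatory scale `B_exc = 2.2`, and
`B_inh = ie_factor * B_exc` for GABA_A (so I/E factor 10 gives
B_inh = 22). The receptor constants `k` (AMPA 1/300, NMDA 1/15000,
ACh 1/3000, GABA_A 1/300) compensate the decay-time ratios so that
`k * tau` is equal across excitatory receptors. Absolute decay
constants are stated only as ratios in the source material
(NMDA : ACh : AMPA = 50 : 10 : 1); the package fixes tau_AMPA =
tau_GABA_A = 2 ms, tau_ACh = 20 ms, tau_NMDA = 100 ms (rise tau_x =
2 ms), all configurable. A glutamatergic synapse instantiates paired
AMPA and NMDA receptors sharing `N`, `B` and one depression variable.
NMDA receptors saturate (`s <= 1`) through the two-variable gating
with activation factor alpha = 0.6332 and carry the
voltage-dependent magnesium block
`1 / (1 + [Mg]/3.57 * exp(-0.062 V))` with [Mg] = 1 mM.

## Short-term depression

`dD/dt = (1 - D)/tau_D - D (1 - p_v) delta(t)`: the depression
variable relaxes to 1 with time constant tau_D and is multiplied by
the vesicle release probability `p_v` at each presynaptic spike
(transmission uses the pre-jump value; the jump precedes the
within-step recovery). `tau_D = 0` disables STD; `p_v` defaults to
0.5, a mid-range release probability, as no value is printed in the
source material. Because D depends only on the presynaptic spike
train, one variable per presynaptic neuron is exactly equivalent to
per-synapse variables with shared parameters — the implementation
exploits this.

A caution on the common mean-field ratio
`1/(1 + (1 - p_v) r tau_D)`: under strictly periodic drive it
describes D *sampled at spike arrival* (within ~2% at 50 Hz,
p_v = 0.5, tau_D = 600 ms) and the time average of a Poisson-driven
synapse, but the continuous time average under periodic drive is
~24% lower, because D dips right after every spike. The tests assert
the exact renewal closed form for the periodic time average and the
mean-field value for the other two readings.

## Numerical integration

The solver is a first-order exponential integrator: the leak is
integrated exactly over each step and synaptic plus noise currents
are held constant within it, so subthreshold leak-only dynamics are
reproduced to machine precision at any dt. The default dt is 0.1 ms
(configurable); all per-step quantities — noise variance, gating
increments, depression jumps — scale correctly with dt, which the
tests check at dt = 0.05/0.1/0.2 ms. Spikes are detected at step
boundaries, reset to V_reset, start the refractory clock, and reach
their targets at the next step boundary (zero transmission delay).
Fast receptors (AMPA, GABA_A, ACh) use the exact linear reduction:
one conductance-weighted gating variable per receptor class per
neuron, algebraically identical to summing per-synapse gating
variables — the identity is asserted to 1e-10 against a per-synapse
reference integration. NMDA gating integrates its nonlinear
`(1 - s)` term by forward Euler within the step, with a saturation
clamp at 1.

Each step caps the membrane change at `|dV| <= dV_max = V_threshold -
V_rev,inh = 25 mV`, applied symmetrically. The cap targets a specific
artifact: a neuron driven far below the GABA_A reversal by massive
inhibition would otherwise receive an enormous *depolarizing*
inhibitory current and fire a spurious rebound spike. With the cap,
any neuron below -70 mV can gain at most 25 mV per step and so cannot
reach threshold from there. The choice of the *inhibitory* reversal
in the cap is the package's own reading (the excitatory reversal
would give 45 mV); it is the one that addresses the artifact.

## Background noise

Each neuron receives an independent Gaussian current per step,
calibrated in closed form so the discrete subthreshold membrane
process (an AR(1)) has stationary mean -60 mV and SD 3 mV:
`mu_I = g_L * 10 mV` and `sigma_I = g_L * 3 mV * sqrt((1 + a)/(1 -
a))` with `a = exp(-dt/tau_m)`. The width scales with g_L, hence with
neuron size, so all neurons share the same resting statistics; the
per-step variance scales like 1/dt, making the stationary statistics
dt-independent. Whether the -60 mV operating point arose in the
source system from a mean current or otherwise is unstated; the
calibration realizes the stated targets either way.

A consequence worth knowing: with the threshold 15 mV (= 5 SD) above
the mean, the spontaneous rate is the first-passage rate of a
strongly correlated process and is exquisitely sensitive to the tail.
Under the exact (-60, 3) calibration the simulated rate at dt =
0.1 ms is ~2.6e-4 Hz — an order of magnitude below the ~4e-3 Hz
sometimes quoted for such settings, which would require an SD near
3.25 mV. The acceptance script reports the rate actually produced by
the calibrated model; the calibration targets and the quoted rate
cannot both hold.

## Synthetic data: what it emulates and what it does not

`synth_skeletons()` plants bipolar neurons — a long, sparsely
branched axonal cable with a terminal tuft and a compact, bushy
dendritic tree — so polarity ground truth is recoverable from the
morphometry by construction. It does not emulate neuropil geometry,
tortuosity or co-localized pre/postsynaptic terminals; passing
polarity tests show the classifier machinery and feature definitions
are coherent, not that real arbors are this separable.

`synth_connectome()` emulates the defining statistics of a
reconstructed brain sample: class shares (~17% cholinergic, 30%
glutamatergic, 39% GABAergic, 14% other), a bimodal projection/local
size distribution, broad in/out-degree distributions via exponential
per-neuron propensities, heavy-tailed contact counts (log-normal body,
Pareto tail), and — critically — a wide, U-shaped per-neuron
excitatory input share (`ei_concentration`), giving many neurons
almost purely excitatory or purely inhibitory input, as reconstructed
brains show and class-blind random networks do not.

The default weight scale deserves an explicit paragraph. At a
test-bench size of ~2,000 neurons (an order of magnitude below a
brain sample) a generator that matched only the *marginal* structural
histograms would produce a network whose recurrent gain is several
times too small to support the dynamical regime that characterizes
these models: a self-sustained hyperactive state at I/E factor 1
(~10^2 Hz), persistence of that state under strong inhibitory
scaling (carried by the nearly-pure-excitatory-input neurons), and
quenching by strong short-term depression. The defaults
(`mean_degree = 95` generated contacts per neuron, leaving a few tens
of connections after the R criterion; `contact_meanlog = log(120)`)
were therefore calibrated to those reported dynamical anchors, at the
cost of contact totals sitting in the upper part of the realistic
span. This is a deliberate scale-down compensation: degree times
weight, not either alone, sets the recurrent gain. Passing the
dynamical tests shows the simulator and model reproduce the regime's
direction on a network *built to be in* that regime; it is not
evidence about any particular real connectome.

One more dynamical honesty note: with a 5-SD threshold gap, the
resting state of these networks is locally stable — spontaneous
noise cannot ignite the hyperactive state within seconds unless
near-suprathreshold "detonator" synapses percolate. The stability
experiments therefore use an ignition protocol:
`run_simulation(..., i_ext = , stim_until = 500)` drives the network
with heterogeneous suprathreshold current for 500 ms and releases it;
hyperactivity onset, persistence and prevalence are measured on the
post-release window. This probes exactly what the stability analyses
characterize — whether hyperactivity persists or is quenched — rather
than its spontaneous onset.

`rewire_network()` builds the randomized control: every synapse keeps
its presynaptic endpoint and conductance while the postsynaptic
endpoint is redrawn uniformly (previously isolated neurons become
eligible, so the randomized network can be slightly larger). Synapse
count, conductance multiset and per-presynaptic out-degrees are
conserved exactly. Collision handling is configurable (resample to
keep distinct pairs, the default, or merge-and-sum) because the
source procedure is silent on it; self-loops are excluded by default.

## Analyses

The E-I index `(N_E - N_I)/(N_E + N_I)` counts distinct presynaptic
partners (unweighted) or sums their contact counts (weighted);
neurons without typed input are reported missing and excluded, with
the exclusion count available. The subsampling control scores a
random subset of neurons on their *full* input sets — the question
being whether merely sampling neurons from a larger random brain
widens the index distribution (it does not, beyond Monte-Carlo
error).

Hyperactivity is whole-population mean rate above 1.0 Hz, measured on
a binned rate trace (default bin 100 ms); episodes are the
above-threshold intervals and prevalence their total duration over
the window, so prevalence and the below-threshold fraction sum to
one exactly. Fano factors are variance/mean of per-trial spike
counts; silent neurons are excluded and counted. Trials are
non-overlapping windows of one run when independent trials are
unavailable; independent-seed trials are used in tests.

Firing-rate distributions are fitted on a log-binned density by
weighted least squares in linear space (weights = bin counts; all
three candidate models are linear in log space, which supplies
starting values for a bounded Levenberg-Marquardt refinement). The
goodness metric `chi2 = sum((obs - fit)^2 / fit)` depends on the
binning, so it ranks models on the same data but is not comparable
across studies; only the model ordering (e.g. truncated power law vs
exponential) is treated as reproducible structure. Planted-parameter
tests recover a truncated-power-law exponent to +-0.2 at n = 10^4.

## Problem sizes used by the test and acceptance suites

Simulation-heavy checks use 1,000 disconnected neurons x 250 s for
the spontaneous-rate measurement, single neurons x 60 s for Vm
statistics, and 2,000-neuron synthetic networks x 6 s for the
stability/depression directions; structural checks use networks of a
few hundred to a few thousand neurons and 100 random skeleton pairs
for the contact-counting oracle. These sizes give Monte-Carlo errors
comfortably inside the asserted tolerances.

## Known limitations

* Polarity: domain splitting is a geometric heuristic; mixed
  (co-innervated) terminals and classifier retraining are out of
  scope.
* Connectomics: warping error of real image registration is not
  modelled; the ROC machinery is validated by self-consistency, not
  against an anatomical reference.
* Dynamics: single-compartment neurons, three fast transmitter
  classes only, no modulatory receptors, no conduction delays; the
  exponential integrator freezes currents within a step, so very
  large conductances are handled through the |dV| cap rather than a
  conductance-exact update.
* The spontaneous-rate / Vm-SD tension described under "Background
  noise" is inherent to the stated calibration targets.
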