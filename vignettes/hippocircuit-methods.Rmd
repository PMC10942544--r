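---
title: "Models and methods behind hippocircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippocircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippocircuit)
```

hippocircuit is a desk-scale toolkit for turning a neuron-type knowledge
base of the rodent hippocampal formation into quantitative circuit models:
a potential connectome, anatomical connection-probability estimates, a
population census, and runnable spiking networks. This vignette explains
the models the package implements, their assumptions, the tunable
parameters, and the numerical choices made where the design was open.

## The parcel registry and laminar codes

The atomic spatial unit is the *parcel*: one layer of one subregion. The
registry fixes 26 parcels across DG (4), CA3 (5), CA2 (4), CA1 (4),
subiculum (3), and entorhinal cortex (6), each subregion with a canonical
layer order. A neuron type's morphology is summarized by one digit per
home-subregion layer — 0 none, 1 axons, 2 dendrites, 3 both — read
positionally against that order:

```{r}
parse_laminar_code("2232", "DG")$presence
```

Parcels invaded outside the home subregion are stored as an explicit
named list rather than by extending the digit string, because the compact
code is conventionally printed for home layers only; the `projecting`
flag is true exactly when that list is non-empty. Marker expression is
three-state (positive / negative / unknown): unknown is never coerced to
negative, since absence of evidence about a marker is common in the
literature and materially different from a negative result.

## Potential connectivity

A directed potential connection from type A to type B exists when at
least one parcel carries both A's axons and B's dendrites. The rule is
binary per parcel — no weighting by neurite length — and type-level
self-edges are kept, because a type whose axons and dendrites share a
parcel can synapse onto other cells of its own type; autapses of
individual cells are excluded later, at wiring. Axonal presence in the
parcel that holds the postsynaptic soma is recorded as a soma-targeting
annotation (a perisomatic contact locus) but is deliberately not an edge
criterion, to keep the edge semantics purely axo-dendritic.

Correctness is guarded by an oracle test: on random fixtures of up to 20
types the edge set must equal an independent brute-force scan that
re-derives the semantics directly from the digit codes.

## Connection probabilities from anatomy

For a pathway with presynaptic axonal length `L_a` (µm) in a parcel and
mean inter-bouton distance `d_ib` (µm), the expected bouton count is
`N_b = L_a / d_ib`. The package then uses a Poisson apposition model:
boutons are treated as uniformly scattered through the axonal arbor's
convex-hull volume `V_hull` (µm³), and a postsynaptic dendrite of length
`L_d` with interaction cross-section `πr²` intercepts on average

```
lambda = N_b * (L_d * pi * r^2) / V_hull
```

appositions. Per ordered cell pair the contact count is Poisson(λ) for
the fraction `f` of pairs whose dendrites lie within the hull, giving

```
p = f * (1 - exp(-lambda))
n_contacts = lambda / (1 - exp(-lambda))   # zero-truncated mean, >= 1
```

λ is additive over parcels (independence across layers). Two knobs are
deliberately exposed for calibration against published
probability/contact tables: the interaction radius `r` (default 1 µm)
and the reachable fraction `f` (default 1; a natural choice is
`V_hull / V_parcel`). `calibrate_pair_estimate()` inverts the
zero-truncated mean by Newton iteration to recover λ, `f`, and `r` from
a published (p, n_contacts) row. Because the published pathway tables
rest on knowledge-base dendritic lengths and hull volumes that are not
part of this package, such agreement is a *calibration* exercise — it
validates the closed forms, not an independent anatomical prediction —
and the tests say so explicitly.

Two pathway conveniences encode documented assumptions: mossy-fiber
estimates (`mossy_fiber_estimates()`) restrict DG Granule innervation to
CA3 stratum lucidum (SL innervation only; SP excluded), with default
inter-bouton distances of 162 µm onto CA3c pyramidal targets, 284 µm
onto other pyramidal targets, and an effective 67.4 µm onto
interneurons (the multi-partner correction is taken as already folded
into that number). Schaffer-collateral estimates
(`schaffer_estimates()`) split the presynaptic total axonal length into
CA1 SR/SP/SO with source-specific fractions and layer-specific
inter-bouton distances, then sum λ over layers. Rows with missing
dendritic lengths are flagged, never silently defaulted.

The model itself is checked against a Monte-Carlo oracle: boutons thrown
uniformly into a box with a straight dendritic segment, counting
appositions within `r`, must match λ within three standard errors.

## The census as weighted nonnegative least squares

Literature-style census facts become linear rows over the unknown
per-type counts `x ≥ 0`: layer totals (`Σ x_i = density × volume`),
marker/morphology fractions (`x_members = fraction × x_group`, encoded
homogeneously), and direct counts. The solver minimizes the weighted sum
of squared residuals subject to nonnegativity (NNLS on the
√weight-scaled system). Two numerical choices matter:

* Fraction rows are homogeneous (target 0) and dimensionless, so with
  unit weights they would be negligible against count-valued rows; by
  default they are rescaled by a crude group-size estimate (the mean
  target of the count rows). This is configurable
  (`fraction_scale = "none"`).
* Counts are real-valued estimates; integer rounding is left to export.

Determinism follows from the NNLS active-set solution; identifiability
is reported from the rank of the stacked coefficient matrix, and types
never referenced by any constraint are flagged rather than silently set
to zero. On consistent full-rank synthetic constraint sets the solver
must recover the generating counts to ≤ 1e-6 relative error.

## Izhikevich neuron dynamics

Each type's input-output function is a nine-parameter single-compartment
Izhikevich model,

```
C dv/dt = k (v - v_r)(v - v_t) - u + I
  du/dt = a (b (v - v_r) - u)
v >= v_peak:  v <- v_min, u <- u + d
```

integrated by explicit forward Euler at `dt = 0.1` ms by default — the
convention of the GPU-oriented spiking simulators these parameter sets
are exported to. The reset is evaluated after each step; the spike
sample is recorded at `v_peak` for plotting. Accuracy is guarded by
refinement tests rather than a fancier integrator: at rest the state is
a machine-exact fixed point, and for the regular-spiking archetype spike
counts over 1 s match a dt/10 reference integration exactly, with
halving dt changing counts by at most one. A known limitation: the
fast-spiking archetype driven hard (≥ 300 pA, ≈100 Hz) shows ~3% count
sensitivity between dt = 0.1 and 0.01 ms; at those rates per-step
discretization of the reset matters more, so analyses of fast-firing
cells that need exact counts should integrate at finer dt.

`f_i_curve()` sweeps current steps (10 pA is the conventional
resolution) and reports rates plus the rheobase, the smallest tested
current evoking a spike. `extract_features()` reduces a trace to resting
potential, threshold estimate (dv/dt ≥ 10 mV/ms), AP amplitude, mean and
maximum rate, first-spike latency, and the adaptation ratio (last ISI /
first ISI, defined from three spikes up).

### The reduced firing-pattern labeler

The full published classification algorithm is out of scope; the package
ships a reduced, deterministic ISI rule set over the phenotypes NASP,
ASP., TSTUT., PSTUT, SLN and the composites TSTUT.SLN and TSTUT.PSTUT.
The explicit thresholds: a steadiness band of ±10% of the median ISI for
NASP; a stutter gap is an ISI above 3× the median; "transient" means
confined to the first 25% of the stimulus; adapting requires the last
ISI at least 30% above the first with a non-decreasing trend. Silence
during the stimulus is SLN, and sub-ISI jitter can never flip a spiking
label to SLN or back, which the property tests exercise.

### Evolutionary-strategy fitting

`fit_izhikevich()` is a (µ+λ) evolutionary strategy (defaults µ=20,
λ=40, Gaussian mutation with σ = 10% of each bound width, elitist joint
selection, mandatory seed). Fitness is the weighted mean of relative
feature errors under the same stimulus as the target. The recovery test
regenerates features from known parameters and refits with µ=12, λ=24
over 40 generations of a 1 s stimulus — enough to bring every fitted
feature (mean rate, latency, adaptation ratio) below 5% error on
multiple seeds. Parameter *identity* is deliberately not required: the
model is over-parameterized for a small feature set, and distinct
parameter vectors reproducing the same behavior are an expected outcome.

## Tsodyks-Pawelzik-Markram synapses

Unitary synaptic signals use the five-constant TPM formulation:
conductance `g`, decay `tau_d`, recovery `tau_r`, facilitation `tau_f`,
utilization `U`, plus a reversal potential (defaults 0 mV excitatory,
-70 mV inhibitory). Between events the state decays analytically
(exactly, so two half-steps equal one full step); at a presynaptic spike
the update order is facilitation first, then release, then resource
consumption:

```
u+ = u + U (1 - u);  release = u+ R;  R <- R - release;  g_t += g * release
```

The order is documented because paired-pulse ratios depend on it. The
post-spike facilitation fixed point under a periodic train has the
closed form `u* = U / (1 - (1-U) e^(-isi/tau_f))`, used as an oracle.
Per-connection amplitudes scale by the contact count
(`g_effective = g × contacts`), since the knowledge-base convention
separates unitary signals from contact counts; the scaling is explicit
in the wiring code and can be disabled by exporting contact counts of 1.
`transfer_strength()` returns `g · tau_d`, the time-integral of a
unit-release transient, used to rank connections by charge transfer.

## Network instantiation and simulation

Populations take their sizes from the census (`round(census × scale)`,
minimum 1). Wiring connects each ordered cell pair of a projection
independently with probability `p` (autapses excluded), and draws
per-synapse contact counts from a shifted Poisson,
`1 + Poisson(n_contacts - 1)`, so the minimum is 1 — contacts per
*connected* pair are at least one by definition — and the mean matches.
Missing projection fields are never filled silently:
`resolve_missing()` substitutes the class-averaged default probabilities
(E-E 0.0117, E-I 0.0237, I-E 0.00684, I-I 0.00423) and documented engine
defaults for synaptic constants, flagging every substituted field
`default`.

The simulation loop is clock-driven for neurons and conductances and
event-driven for synaptic state: per-projection conductance accumulators
decay by `exp(-dt/tau_d)` each step and receive delayed releases from a
ring buffer; TPM per-synapse state is updated lazily (analytically) only
when its presynaptic cell fires. Delays default to a uniform 1 ms
(configurable per projection) and live on the dt grid. Wiring and drive
use separate RNG streams, so changing the drive seed leaves the
adjacency untouched, and identical seeds give bitwise-identical rasters.
A one-neuron network reproduces the standalone integrator sample for
sample, which pins the composition of the two code paths.

### LFP proxy and band filtering

How the reference resting-state figures computed their field potential
is not specified, so the package states its own stand-in: the LFP proxy
is the summed absolute synaptic current onto excitatory cells. Filtering
uses a 4th-order Butterworth band-pass applied forward-backward (zero
phase) with the preset bands theta 4–12 Hz, gamma 25–100 Hz, ripple
150–200 Hz. One numerical point: at a 10 kHz sampling rate the 4–12 Hz
band normalizes to ~1e-3 of Nyquist, where a 4th-order transfer-function
Butterworth is numerically unstable. `lfp_filter()` therefore decimates
(anti-aliased, factors ≤ 10) to a working rate of about 40× the band's
upper edge, filters there, and interpolates linearly back to the
original grid. An 8 Hz test tone must retain ≥ 90% amplitude through the
theta band and leak ≤ 5% through the ripple band.

### The CA3-like demonstration network

`run_ca3_demo()` builds an eight-type analogue of a resting-state CA3
circuit: 2800 Pyramidal cells plus seven interneuron types (Axo-axonic,
Basket, Basket CCK+, Bistratified, Ivy, MFA ORDEN, QuadD-LM) at 100
cells each — 3500 cells, a deliberate desk-scale size. Dynamics use the
regular-/fast-spiking archetypes, wiring the class-default
probabilities, synapses the engine defaults, and the drive is noisy
constant current (Pyramidal 90 ± 60 pA, interneurons 130 ± 50 pA),
chosen once for plausible resting rates. One simulated second takes
roughly half a minute on one CPU. The demo shows that the assembled
pipeline sustains activity in every population with finite power in all
three bands; it is a qualitative analogue, not a reproduction of any
published full-scale simulation.

## What the synthetic knowledge base does and does not emulate

`generate_fixture_kb()` reproduces the *structure* of a curated
knowledge base: laminar codes over the registry (with a shared
axon+dendrite hub layer per subregion guaranteeing a non-empty
connectome), Izhikevich parameters within ±10% of the archetypes, TPM
constants in physiological ranges (g 0.2–2 nS, tau_d 3–20 ms, tau_r
200–800 ms, tau_f 20–200 ms, U 0.1–0.5), connection probabilities
0.005–0.03, census counts of 3000–8000 (excitatory) and 150–900
(inhibitory) per type, and a consistent full-rank constraint set
encoding those counts. It does not emulate the statistical dependencies
of real data — correlated laminar patterns across related types,
heavy-tailed census distributions, covariate structure in synaptic
constants, or inconsistent/conflicting literature constraints. Tests
passing on fixtures therefore demonstrate algorithmic correctness and
determinism, not that the package's defaults reproduce any particular
biological circuit.

## Degenerate inputs and tie-breaks

Laminar codes of the wrong length or alphabet fail naming the position;
`pair_estimate()` refuses λ ≤ 0 (the truncated mean is undefined there);
fraction constraints that cancel to an all-zero row are rejected;
unresolved projection fields abort instantiation rather than defaulting;
non-finite voltages abort the run naming the cell and time. In the
labeler, a single spike after the transient window is NASP by
convention (one spike has no ISI structure), and between the strict
NASP and ASP. bands the label follows the ISI trend.
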