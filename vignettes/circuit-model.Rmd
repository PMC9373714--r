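---
title: "The dacircuit model: biophysics, dopamine modulation, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dacircuit model: biophysics, dopamine modulation, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The circuit and what it is for

`dacircuit` simulates a small mesocorticolimbic circuit — the medial
prefrontal cortex (mPFC) and nucleus accumbens (NAc) under a dopamine input
that stands in for the ventral tegmental area (VTA) — to study how a
depressed dopamine tone reshapes firing patterns, synaptic currents and
local field potentials.  Major depressive disorder is modelled as the low
end of a dopamine axis: the dopamine level is a scalar `k` in [0, 100]%,
with 0% the depression-like (MDD) condition and 100% the normal condition.
The VTA itself is not simulated as spiking units; its output is the level
`k`, which deterministically re-parameterises a handful of ion channels
(see *Dopamine as a parameter interpolator* below).

The default network has 28 neurons: 16 pyramidal cells (PYR), 2
parvalbumin (PV) and 2 calbindin (CB) interneurons in mPFC (preserving the
4:1 pyramidal-to-interneuron ratio), and 4 D2-type medium spiny neurons
(MSN), 2 PV and 2 CB interneurons in NAc.  Pyramidal cells release
glutamate onto all interneurons and onto MSN dendritic spines (AMPA +
NMDA); interneurons release GABA onto the pyramidal or MSN somata of their
own region; MSN output leaves the simulated circuit (it targets the VTA).
Only the total of 28 and the 4:1 ratio are fixed points of the design; the
per-population split and the edge list live in
`inst/extdata/params/network.yaml` and can be overridden wholesale.

## Membrane model

Every compartment obeys a Hodgkin–Huxley current balance

$$C_m \frac{dV}{dt} + \sum I_{ion} + \sum I_{compartment} + \sum I_{synapse}
  = I_{stimuli},$$

with currents as densities (µA/cm²) and $C_m$ = 1 µF/cm².  Voltage-gated
currents are either ohmic, $I = \bar g\, m^x h^y (V - E)$, partially
inactivating, $I = \bar g\, m^x (a h - (1-a)) (V - E)$ with $a \in [0,1]$
(the MSN slow A-type current KAs), or constant-field calcium fluxes
computed with the Goldman–Hodgkin–Katz equation (valence 2, F = 96 489
C/mol, R = 8.31 J/(K·mol), T = 35 °C, [Ca]out = 5 mM).  Near V = 0 the GHK
form is evaluated by its two-term Taylor expansion (switch at
|zFV/RT| < 1e-4), which makes the current continuous and reproduces the
L'Hôpital limit $PzF([Ca]_{in} - [Ca]_{out})$ exactly at V = 0.

Gates follow first-order kinetics $dm/dt = (m_\infty(V) - m)/\tau(V)$ with
Boltzmann steady states $m_\infty = 1/(1 + e^{(V - V_{1/2})/k})$.  The
slope $k$ is signed and stated explicitly in the parameter files —
activation gates carry negative slopes, inactivation gates positive slopes,
and the MSN inward rectifier (KIR) is an "activation" gate with a positive
slope because it genuinely opens on hyperpolarisation.  Time constants are
either scalars or voltage tables interpolated linearly and clamped at the
table ends.

Two potassium conductances (the BK/SK family) are gated by submembrane
calcium rather than voltage.  The gate framework therefore supports a
second gate kind, a Hill function $m_\infty = [Ca]^n/([Ca]^n + K_d^n)$ of
the local calcium pool.  This is an extension beyond a purely
voltage-Boltzmann gate set; without it the MSN 15-channel complement and
the pyramidal after-burst pause could not be expressed.

### Calcium pools and units

Each compartment with calcium channels carries a thin-shell pool

$$\frac{d[Ca]}{dt} = k\frac{-I_{Ca}}{2Fd}
  - p\,K_t \frac{[Ca]}{[Ca]+K_d} + \frac{[Ca]_\infty - [Ca]}{\tau_R},$$

with d = 0.1 µm, $K_t = K_d$ = 1e-4, $\tau_R$ = 43 ms, k = 1000, p = 0.02,
initial [Ca] = 0.001 mM.  The resting target $[Ca]_\infty$ is not stated
in the sources; the package sets it equal to the initial value (0.001 mM),
flagged here as an assumption.  The influx term's printed constants are
dimensionally consistent only if the current is expressed in mA/cm² with d
in µm; `ca_pool_derivative()` therefore declares its current argument in
mA/cm² and the network core converts its µA/cm² channel currents by 1e-3
before driving pools.  With these conventions the effective flux factor is
~5.2e-5 mM/ms per µA/cm², the standard submembrane-shell value, and a
single action potential raises shell calcium by a few tenths of a µM.

### Compartment coupling

Adjacent compartments exchange current through the directional Rall-type
conductance

$$g_{a \leftarrow b} = \frac{d_a d_b^2}{r_L\, l_a\,(d_a^2 l_b + d_b^2 l_a)},$$

evaluated once per direction (receiver's geometry in the first slot), so
pairwise currents are *not* exactly antisymmetric; the package keeps the
formulation as printed rather than symmetrising it, and the test suite
asserts the directional values rather than conservation.  With lengths in
µm and $r_L$ in Ω·cm the conversion to mS/cm² of receiving membrane is a
factor 1e7, applied once in the network compiler.

## Neuron templates

Four templates ship in editable YAML files (`inst/extdata/params/`), the
single source of truth for all kinetics:

* **MSN** — 1 soma + 10 identical dendritic-spine compartments in a star;
  15 channel types of the Wolf-type MSN family (NaF, NaP, KAf, KAs, KIR,
  KRP, BK, SK, and six GHK calcium channels CaL1.2, CaL1.3, CaN, CaQ, CaR,
  CaT, plus leak).  KIR holds the down-state near −85 mV; strong input is
  needed to reach threshold, giving the sparse firing characteristic of
  striatal projection neurons.
* **PYR** — soma–proximal–distal chain (no basal dendrite); 8 channel
  types of the Durstewitz-type PFC family (Na, Kdr, NaP, KS, HVA Ca, CaN,
  SK-type KCa, leak).  Bursting arises from the NaP/Ca/SK loop: persistent
  sodium drives rapid re-firing, calcium accumulates through the GHK
  channels, SK terminates the cluster, and the pool's 43-ms recovery sets
  the ~100 ms interburst interval.
* **PV** — single compartment, 3 channel types (fast Na, fast delayed
  rectifier, leak), the classic fast-spiking configuration.
* **CB** — single compartment, 6 channel types (Na, Kdr, A-type K, CaN,
  SK-type KCa, leak), an adapting interneuron.

Because the original supplementary parameter tables are unavailable, the
kinetics were transcribed from the cited model families and then adjusted
so the isolated templates reproduce the intended firing classes with the
default stimuli — a calibration recorded entirely in the YAML files.  Two
systematic adjustments deserve mention: sodium activation midpoints sit
near −35 mV with inactivation midpoints near −48 mV (so enough h remains
available at threshold for reliable spiking at 0.02 ms steps), and maximal
sodium conductances stay at or below ~100 mS/cm² so that the fastest
membrane eigenvalue times the step stays inside the explicit integrator's
stability region (an MSN NaF of 150 mS/cm² produces single-step overshoot
of the spike peak).

## Synapses

AMPA, NMDA and GABA-A receptors follow the Destexhe two-state kinetic
scheme: open fraction $dr/dt = \alpha [T](1-r) - \beta r$ with a sigmoidal
transmitter pulse $[T] = T_{max}/(1 + e^{-(V_{pre}-V_p)/K_p})$
($T_{max}$ = 1 mM, $V_p$ = 2 mV, $K_p$ = 5 mV), and currents
$I = \bar g r (V - E)$, the NMDA current additionally multiplied by the
magnesium block $B(V) = 1/(1 + e^{-(V+15)/16.3})$.  Rate constants are the
Destexhe values (AMPA α = 1.1 mM⁻¹ms⁻¹, β = 0.19 ms⁻¹; NMDA α = 0.072,
β = 0.0066; GABA-A α = 5, β = 0.18).  Each directed cell pair and receptor
kind carries one connection weight drawn from U(0, 1) under the trial's
weight seed.  Conductances are densities of postsynaptic membrane;
glutamatergic input to MSNs lands on spines round-robin, GABA on somata.
There are no transmission delays and no synaptic plasticity, and dopamine
never touches receptor parameters — it acts only through ion channels.

## Dopamine as a parameter interpolator

A parameter with endpoint values $a$ (at 0%) and $b$ (at 100%) takes the
value $a + (b-a)k/100$ at level $k$.  The shipped rule set
(`dopamine_rules.yaml`) covers: pyramidal HVA Ca and CaN permeabilities of
soma and distal dendrite (reduced by dopamine), the proximal-dendrite KS
conductance (reduced), and the proximal NaP gating (activation shifted
left, inactivation shifted right — net excitatory); and on the D2-MSN side
the KAs conductance (increased) and CaL1.2 permeability (reduced).  The
sources state *which* parameters dopamine touches but not the endpoint
numbers, and for NaP not even which gating parameter; the rules target the
half-activation voltages by default, and all endpoints were calibrated so
the network reproduces the qualitative dose–response: pyramidal firing
rate and burst count rise with dopamine, pyramidal mean membrane potential
falls (the interneuron-mediated balance effect), PV firing rises, and MSN
firing is insensitive.  Applying a rule always interpolates from its
stored endpoints, so modulation is idempotent and never compounds.

In `uniform_range` schedules a single level is drawn per trial and held
constant — dopamine has no within-trial dynamics.

## Stimuli, integration and reproducibility

Stimulus currents are uniform draws $U[min, max]$ per neuron, redrawn every
integration step, zero outside the 500–3500 ms window.  The intervals are
per population and are calibration constants: interneurons receive little
direct drive (≤ 4 µA/cm² at the soma) so that their activity is mostly
pyramidal-driven, pyramidal cells receive up to 7 µA/cm², and MSNs up to
180 µA/cm² — a large density because the stimulus enters the soma while
the spiny tree (ten times the somatic area) loads it; at an MSN soma of
~800 µm² the interval corresponds to ~0–1.4 nA, i.e. a physiological
rheobase scale.

The integrator is the Bogacki–Shampine explicit Runge–Kutta 2(3) pair run
at a fixed 0.02 ms step (an effective 50 kHz sampling); the third-order
solution is propagated and the embedded second-order solution yields a
logged error estimate (computed every 200 steps by default).  All states —
voltages, gates, receptor fractions, calcium — are integrated jointly.
After each step gates and receptor fractions are clamped to [0, 1] and
calcium to a positive floor; these are inactive safeguards on the shipped
protocols and exist to keep pathological parameter sets diagnosable (a
voltage outside ±1000 mV raises a blow-up error naming the state and
time).  Every trial is identified by a derived (weights, stimulus,
dopamine) seed triple, and the compiled core draws its stimulus stream from
its own counter-based generator, so recordings are bit-identical across
runs and platforms for a given protocol seed.

The full-network right-hand side exists twice: once in C++ (the production
core) and once in plain R built from the package's scalar operations; the
test suite requires the two to agree to 1e-10 at reference and perturbed
states, which guards the compiled code against transcription drift.

## Analysis conventions

* **Spikes** — upward crossings of 0 mV with a 2 ms lockout (neither value
  is stated in the sources; both are configurable).
* **Bursts** — a burst opens at an interspike interval ≤ 40 ms, extends
  while intervals stay ≤ 100 ms, closes at the first longer interval, and
  must contain at least two spikes.  The boundary conventions (≤ on both
  bounds, strict > to close, no single-spike bursts) are package choices
  where the quoted rule is ambiguous.
* **Mean peak potential** — mean over spikes of the local voltage maximum
  within ±2 ms of each spike; interpreted as mean *peak voltage* (so it is
  translation-equivariant) rather than amplitude above threshold.
* **Peak statistics of currents** — per-spike extremum of the aligned
  current (largest absolute excursion within ±2 ms); the peak frequency
  equals the spike frequency by construction.
* **IQR filter** — keeps values between the 25th and 75th percentile
  inclusive, type-7 (linear interpolation) percentiles.
* **Firing-rate window** — the 500–3500 ms stimulus window.

## Spectral conventions

The LFP is the arithmetic mean (not the sum, so units stay in mV and the
value is count-invariant) of the 28 somatic potentials, resampled from
50 kHz to 500 Hz by staged Butterworth anti-aliasing (8th order effective,
zero-phase, reflection-padded — a constant trace passes through exactly)
and decimation.  PSDs are Welch estimates: 2048-point Hann segments at 50%
overlap, demeaned, with Parseval-consistent one-sided scaling, giving
exactly N = 1024 grid points on 0–250 Hz; a single-segment periodogram is
available as an option.  The source text states only that an FFT was
taken, but the stated N = 1024 over 0–250 Hz at 500 Hz forces a 2048-point
transform; segment averaging is the package's choice of estimator.  The
STFT uses 100 ms windows (50 samples) at 50% overlap with times at window
centers.

dBm/Hz values are $10\log_{10}(P_W)$ applied to the PSD value as printed,
with no milliwatt reference rescaling.  Group comparison is a
per-frequency two-sample t-test on dBm values across trials (Welch's
unequal-variance form by default, pooled available), significance level
α = 0.1; `DiffRatio` is the fraction of the 1024 frequencies with
p < α.  Identical groups produce 0/0 t-statistics, which count as *not*
significant.  ΔP maps are elementwise dBm differences; the conventional
[−20, 20] display clipping is left to plotting code, raw values are
returned.  The per-frequency tests are run across trials (not across time
windows), matching the trial-count n's of the experiment designs.

## Experiment designs and problem sizes

`run_experiment("quartiles")` runs the four random dopamine ranges (0–25,
25–50, 50–75, 75–100%) × 3 trials; `run_experiment("fixed5")` runs the
five fixed levels (0, 25, 50, 75, 100%) × 6 trials.  The package's own
verification (test suite and `scripts/acceptance.R`) contrasts 0% vs 100%
with 3 trials per condition at the full 4 s / 0.02 ms resolution, which is
the scale at which the directional effects are stable per-seed; the
original figure-level statistics (n = 180 cells over many replications)
are an order of magnitude more simulation than a package check needs, and
point-value F/p statistics are not reproduction targets here.

## What the synthetic conditions do and do not show

All inputs are synthetic: uniform noise stimuli, uniform random weights,
deterministic dopamine levels.  Passing checks therefore demonstrate that
the *model* produces the documented dopamine-dependent physiology under
its stated conditions — they do not validate the kinetics against
recordings, and real tissue has correlated inputs, conduction delays,
plasticity, D1-MSNs and interneuron diversity that the model explicitly
omits.  Within the model, the known limitations are: channel kinetics are
composites of their source families rather than fits to data; the
0.02 ms explicit integrator constrains maximal conductances (see above);
spine compartments are identical by construction; and the LFP is a somatic
mean rather than a volume-conducted field.
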