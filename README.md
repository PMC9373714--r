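# dacircuit

Biophysical simulation of the dopamine-modulated VTA–NAc–mPFC
microcircuit, for computational studies of depression-like (low-dopamine)
states.

Depressed dopamine tone in the mesocorticolimbic pathway — ventral
tegmental area (VTA) → nucleus accumbens (NAc) and medial prefrontal
cortex (mPFC) — is a core physiological signature of major depressive
disorder. `dacircuit` implements a 28-neuron Hodgkin–Huxley network of
this circuit in which dopamine is a direct scalar input: a level
k ∈ [0, 100]% linearly re-parameterises a small set of dopamine-sensitive
ion channels between their dopamine-depleted (k = 0, "MDD") and normal
(k = 100) values,

> param(k) = a + (b − a) · k/100,

while everything else — kinetics, synapses, wiring — stays fixed. The
package is aimed at computational neuroscientists who want to run,
extend, or re-parameterise the dopamine-gradient experiments at desk
scale.

## What is inside

* **Cells** — multi-compartment Hodgkin–Huxley templates: D2-type medium
  spiny neurons (1 soma + 10 dendritic spines, 15 channel types,
  Wolf-type kinetics), mPFC pyramidal cells (soma–proximal–distal chain,
  8 channel types, Durstewitz-type kinetics, NaP/Ca/SK burst mechanism),
  and PV / CB interneurons (3 / 6 channel types). Currents are ohmic
  (`g·mˣ·hʸ·(V−E)`), partially inactivating (`g·mˣ·(a·h−(1−a))·(V−E)`),
  or Goldman–Hodgkin–Katz calcium fluxes with submembrane calcium pools.
  All parameters live in editable YAML files under
  `inst/extdata/params/`.
* **Synapses** — Destexhe two-state kinetic AMPA / NMDA (with Mg²⁺
  block) / GABA-A receptors; one U(0, 1) connection weight per directed
  cell pair.
* **Network** — the default manifest wires 16 PYR + 2 PV + 2 CB (mPFC,
  the 4:1 ratio) and 4 MSN + 2 PV + 2 CB (NAc); glutamate from pyramidal
  cells onto interneurons and MSN spines, GABA onto somata; uniform noise
  stimuli in a 500–3500 ms window.
* **Simulation** — fixed-step Bogacki–Shampine Runge–Kutta 2(3) at
  dt = 0.02 ms in a compiled core; fully seeded (weights, stimulus,
  dopamine) so every trial is bit-reproducible.
* **Analysis** — spike detection, the 40/100 ms interspike-interval burst
  rule, firing rates, mean membrane / peak potentials, spike-aligned
  peak-current statistics, IQR filtering, rate–dopamine regression,
  current–voltage correlations.
* **Spectra** — local field potential (mean somatic voltage resampled to
  500 Hz), Welch / periodogram PSDs on a 1024-point 0–250 Hz grid, STFT
  (100 ms windows, 50% overlap), dBm/Hz conversion, per-frequency t-tests
  with the DiffRatio summary (α = 0.1), ΔP dBm difference maps, and
  gamma-band summaries.

## Worked example

```r
library(dacircuit)

net <- build_network(load_manifest(), weight_seed = 1)
net
#> da_network: 28 neurons, 464 synaptic edges
#>        CB MSN PV PYR
#>   mPFC  2   0  2  16
#>   NAc   2   4  2   0

p   <- simulation_protocol(duration = 4000,
                           da = dopamine_schedule("fixed", level = 100),
                           seed = 1)
rec <- run_trial(load_manifest(), p, trial = 1, condition = 2)
rec
#> recording: 4000 ms, 200001 samples, 28 voltage traces, DA = 100 %

pyr <- which(rec$neurons$kind == "PYR")
median(sapply(pyr, function(i) firing_rate(rec$spikes[[i]])))
#> [1] 8.666667          # median pyramidal rate, Hz (stimulus window)
median(sapply(pyr, function(i) nrow(detect_bursts(rec$spikes[[i]]))))
#> [1] 5.5               # median pyramidal burst count per trial

psd <- compute_psd(make_lfp(rec), method = "periodogram")
to_dbm(band_power(psd, c(30, 50)))    # low-gamma LFP power, dBm/Hz
#> [1] -9.87
to_dbm(band_power(psd, c(50, 100)))   # high-gamma LFP power, dBm/Hz
#> [1] -14.32
```

Re-running the same protocol at `dopamine_schedule("fixed", level = 0)`
(the MDD condition) collapses the median pyramidal rate to ~1 Hz with no
bursts and raises the pyramidal mean membrane potential — the
depression-like phenotype the model is built around — while MSN firing
rates barely move.

## Documentation

The methods vignette (`vignettes/circuit-model.Rmd`) documents the model
equations and assumptions, the unit conventions, the dopamine modulation
rules, the calibration choices behind the shipped parameter files, the
numerical scheme, and known limitations.
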