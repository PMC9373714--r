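# Parvalbumin interneuron: single compartment, 3 channel types
# (Wang-Buzsaki-type fast-spiking kinetics: fast Na recovery, fast
# delayed rectifier; fires high-rate tonic trains).
neuron: PV
v_init: -65
c_m: 1.0
r_l: 150
adjacency: none
compartments:
  - name: soma
    length: 15
    diameter: 15
    channels: [Na, Kdr, Leak]
channels:
  Na:
    mode: ohmic
    e_rev: 55
    g_max: 100
    activation: {power: 3, v_half: -35, slope: -6, tau: 0.05}
    inactivation: {power: 1, v_half: -48, slope: 6, tau: 0.5}
  Kdr:
    mode: ohmic
    e_rev: -90
    g_max: 80
    activation: {power: 4, v_half: -30, slope: -9, tau: 0.6}
  Leak:
    mode: ohmic
    e_rev: -65
    g_max: 0.1
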