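# Calbindin interneuron: single compartment, 6 channel types; an adapting
# interneuron (A-type potassium plus N-type calcium feeding an SK-type
# calcium-gated potassium conductance).
neuron: CB
v_init: -65
c_m: 1.0
r_l: 150
adjacency: none
compartments:
  - name: soma
    length: 15
    diameter: 15
    ca_pool: true
    channels: [Na, Kdr, KA, CaN, KCa, Leak]
channels:
  Na:
    mode: ohmic
    e_rev: 55
    g_max: 70
    activation: {power: 3, v_half: -35, slope: -6, tau: 0.05}
    inactivation: {power: 1, v_half: -48, slope: 6, tau: 1.0}
  Kdr:
    mode: ohmic
    e_rev: -90
    g_max: 50
    activation: {power: 4, v_half: -30, slope: -9, tau: 1.5}
  KA:
    mode: ohmic
    e_rev: -90
    g_max: 3
    activation: {power: 1, v_half: -40, slope: -8, tau: 1}
    inactivation: {power: 1, v_half: -70, slope: 6, tau: 30}
  CaN:
    mode: ghk
    p_max: 1.0e-6
    activation: {power: 2, v_half: -18, slope: -7, tau: 1}
    inactivation: {power: 1, v_half: -40, slope: 12, tau: 70}
  KCa:
    mode: ohmic
    e_rev: -90
    g_max: 2
    activation: {power: 1, kind: ca, kd: 0.0025, hill: 4, tau: 8}
  Leak:
    mode: ohmic
    e_rev: -65
    g_max: 0.1
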