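# mPFC pyramidal neuron: soma - proximal dendrite - distal dendrite chain
# (basal dendrites not modelled).  8 channel types.  Kinetics follow the
# Durstewitz-type PFC pyramidal cell family (Boltzmann gates); conductance
# densities adjusted so the isolated cell fires Ca/KCa-paced spike bursts
# under the demo stimulus.  Dopamine-sensitive endpoints live in
# dopamine_rules.yaml; the values here are the normal (100%) condition.
neuron: PYR
v_init: -70
c_m: 1.0
r_l: 150          # Ohm*cm
adjacency: chain
compartments:
  - name: soma
    length: 20
    diameter: 20
    ca_pool: true
    channels: [Na, Kdr, NaP, KS, Ca, CaN, KCa, Leak]
  - name: proximal
    length: 150
    diameter: 3
    channels: [Na, Kdr, NaP, KS, Leak]
  - name: distal
    length: 300
    diameter: 2
    ca_pool: true
    channels: [Na, Kdr, Ca, CaN, KCa, Leak]
channels:
  Na:
    mode: ohmic
    e_rev: 55
    g_max: {soma: 80, proximal: 15, distal: 8}
    activation: {power: 3, v_half: -35, slope: -6, tau: 0.06}
    inactivation:
      power: 1
      v_half: -48
      slope: 6
      tau:                    # voltage-dependent recovery, tabulated
        v: [-90, -60, -40, 0]
        tau: [1.2, 1.5, 1.0, 0.4]
  Kdr:
    mode: ohmic
    e_rev: -90
    g_max: {soma: 60, proximal: 10, distal: 6}
    activation: {power: 4, v_half: -32, slope: -9, tau: 2.5}
  NaP:                        # persistent sodium; DA shifts its gating
    mode: ohmic
    e_rev: 55
    g_max: {soma: 0.2, proximal: 0.45}
    activation: {power: 1, v_half: -53, slope: -5, tau: 1}
    inactivation: {power: 1, v_half: -52, slope: 7, tau: 1000}
  KS:                         # slowly inactivating potassium; DA lowers g
    mode: ohmic
    e_rev: -90
    g_max: {soma: 0.4, proximal: 0.5}
    activation: {power: 1, v_half: -34, slope: -6.5, tau: 6}
    inactivation: {power: 1, v_half: -65, slope: 6.6, tau: 300}
  Ca:                         # high-voltage-activated calcium, GHK flux
    mode: ghk
    p_max: {soma: 6.0e-6, distal: 2.0e-6}
    activation: {power: 2, v_half: -12, slope: -6, tau: 1.5}
  CaN:                        # N-type calcium, GHK flux
    mode: ghk
    p_max: {soma: 1.2e-6, distal: 0.6e-6}
    activation: {power: 2, v_half: -18, slope: -7, tau: 1}
    inactivation: {power: 1, v_half: -40, slope: 12, tau: 70}
  KCa:                        # SK-type calcium-gated potassium
    mode: ohmic
    e_rev: -90
    g_max: {soma: 6, distal: 2}
    activation: {power: 1, kind: ca, kd: 0.0025, hill: 4, tau: 8}
  Leak:
    mode: ohmic
    e_rev: -70
    g_max: 0.1
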