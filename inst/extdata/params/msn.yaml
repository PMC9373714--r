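# D2-type medium spiny neuron of the NAc: 1 soma + 10 identical dendritic
# spine compartments in a star.  15 channel types following the Wolf-type
# MSN model family: fast/persistent sodium, fast and slow A-type potassium
# (the slow one partially inactivating), inward rectifier (sets the
# hyperpolarised ~-85 mV down-state), persistent potassium, BK/SK
# calcium-gated potassium, and six GHK-flux calcium channels.  The KAs and
# CaL1.2 entries here are the normal (100% dopamine) values; endpoints in
# dopamine_rules.yaml.
neuron: MSN
v_init: -85
c_m: 1.0
r_l: 150
adjacency: star
compartments:
  - name: soma
    length: 16
    diameter: 16
    ca_pool: true
    channels: [NaF, NaP, KAf, KAs, KIR, KRP, BK, SK,
               CaL1.2, CaL1.3, CaN, CaQ, CaR, CaT, Leak]
  - name: spine
    count: 10
    length: 120
    diameter: 2
    ca_pool: true
    channels: [NaF, NaP, KAf, KAs, KIR, KRP, SK,
               CaL1.2, CaL1.3, CaQ, CaR, CaT, Leak]
channels:
  NaF:
    mode: ohmic
    e_rev: 55
    g_max: {soma: 90, spine: 25}
    activation: {power: 3, v_half: -32, slope: -7, tau: 0.05}
    inactivation: {power: 1, v_half: -45, slope: 7, tau: 1.5}
  NaP:
    mode: ohmic
    e_rev: 55
    g_max: {soma: 0.03, spine: 0.01}
    activation: {power: 1, v_half: -52.6, slope: -4.6, tau: 3}
  KAf:
    mode: ohmic
    e_rev: -90
    g_max: {soma: 20, spine: 8}
    activation: {power: 2, v_half: -33, slope: -7.5, tau: 0.5}
    inactivation: {power: 1, v_half: -70, slope: 7, tau: 25}
  KAs:                       # slow A-type, partially inactivating (a = 0.8)
    mode: partial
    partial_fraction: 0.8
    e_rev: -90
    g_max: {soma: 4.4, spine: 3.0}
    activation: {power: 2, v_half: -27, slope: -16, tau: 10}
    inactivation: {power: 1, v_half: -34, slope: 21, tau: 1000}
  KIR:                       # inward rectifier: opens on hyperpolarisation
    mode: ohmic
    e_rev: -90
    g_max: {soma: 0.35, spine: 0.3}
    activation: {power: 1, v_half: -82, slope: 13, tau: 0.5}
  KRP:                       # persistent (resistant) potassium
    mode: ohmic
    e_rev: -90
    g_max: {soma: 1.0, spine: 0.5}
    activation: {power: 1, v_half: -13.5, slope: -11.8, tau: 5}
    inactivation: {power: 1, v_half: -55, slope: 19, tau: 3000}
  BK:
    mode: ohmic
    e_rev: -90
    g_max: {soma: 2}
    activation: {power: 1, kind: ca, kd: 0.004, hill: 2, tau: 1}
  SK:
    mode: ohmic
    e_rev: -90
    g_max: {soma: 2, spine: 1}
    activation: {power: 1, kind: ca, kd: 0.0025, hill: 4, tau: 8}
  CaL1.2:                    # Cav1.2 L-type, GHK flux; DA-sensitive
    mode: ghk
    p_max: {soma: 2.8e-6, spine: 1.4e-6}
    activation: {power: 1, v_half: -8.9, slope: -6.7, tau: 1.5}
  CaL1.3:                    # Cav1.3 low-threshold L-type
    mode: ghk
    p_max: {soma: 2.0e-6, spine: 1.0e-6}
    activation: {power: 1, v_half: -33, slope: -6.7, tau: 1.5}
  CaN:
    mode: ghk
    p_max: {soma: 3.0e-6}
    activation: {power: 2, v_half: -10, slope: -7, tau: 1}
    inactivation: {power: 1, v_half: -74.8, slope: 6.5, tau: 70}
  CaQ:
    mode: ghk
    p_max: {soma: 2.0e-6, spine: 1.0e-6}
    activation: {power: 2, v_half: -9, slope: -6.6, tau: 1.5}
  CaR:
    mode: ghk
    p_max: {soma: 2.0e-6, spine: 1.0e-6}
    activation: {power: 3, v_half: -10.3, slope: -6.6, tau: 1.7}
    inactivation: {power: 1, v_half: -33.3, slope: 17, tau: 20}
  CaT:
    mode: ghk
    p_max: {soma: 1.0e-6, spine: 0.5e-6}
    activation: {power: 3, v_half: -51.7, slope: -6.5, tau: 2}
    inactivation: {power: 1, v_half: -80, slope: 6.4, tau: 15}
  Leak:
    mode: ohmic
    e_rev: -75
    g_max: 0.05
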