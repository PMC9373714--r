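# Dopamine modulation rules: each parameter is linearly interpolated
# between its 0% (dopamine-depleted / depression-like) and 100% (normal)
# endpoint, a + (b - a) * k/100.
#
# Pyramidal neurons (D1-type action, Durstewitz-type endpoints): dopamine
# lowers the HVA Ca and CaN permeabilities of soma and distal dendrite,
# lowers the slowly inactivating KS conductance of the proximal dendrite,
# and shifts the persistent-sodium (NaP) activation leftward / inactivation
# rightward on the proximal dendrite (net excitatory).
#
# D2-MSNs (D2-type action, Wolf-type endpoints): dopamine raises the slow
# A-type KAs conductance and lowers the Cav1.2 permeability of soma and
# spines.
#
# Receptor (synaptic) parameters are deliberately absent: dopamine never
# alters mEPSC/mIPSC parameters directly in this model.
rules:
  - {kind: PYR, compartment: soma,     channel: Ca,     path: p_max,
     at0: 1.0e-5, at100: 6.0e-6}
  - {kind: PYR, compartment: distal,   channel: Ca,     path: p_max,
     at0: 3.2e-6, at100: 2.0e-6}
  - {kind: PYR, compartment: soma,     channel: CaN,    path: p_max,
     at0: 2.0e-6, at100: 1.2e-6}
  - {kind: PYR, compartment: distal,   channel: CaN,    path: p_max,
     at0: 1.0e-6, at100: 0.6e-6}
  - {kind: PYR, compartment: proximal, channel: KS,     path: g_max,
     at0: 1.2,   at100: 0.5}
  - {kind: PYR, compartment: proximal, channel: NaP,    path: activation.v_half,
     at0: -46,   at100: -53}
  - {kind: PYR, compartment: proximal, channel: NaP,    path: inactivation.v_half,
     at0: -56,   at100: -52}
  - {kind: MSN, compartment: soma,     channel: KAs,    path: g_max,
     at0: 3.0,   at100: 4.4}
  - {kind: MSN, compartment: spine,    channel: KAs,    path: g_max,
     at0: 2.0,   at100: 3.0}
  - {kind: MSN, compartment: soma,     channel: CaL1.2, path: p_max,
     at0: 4.0e-6, at100: 2.8e-6}
  - {kind: MSN, compartment: spine,    channel: CaL1.2, path: p_max,
     at0: 2.0e-6, at100: 1.4e-6}
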