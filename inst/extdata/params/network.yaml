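# Default 28-neuron NAc-mPFC circuit manifest.
#
# Stated constraints: 28 neurons total; mPFC pyramidal:interneuron ratio
# 4:1.  The per-population split (16 PYR + 2 PV + 2 CB in mPFC, 4 D2-MSN +
# 2 PV + 2 CB in NAc) and the edge list are assumptions consistent with the
# circuit's anatomy (glutamate from pyramidal cells onto interneurons and
# MSN spines; GABA from local interneurons onto pyramidal/MSN somata; MSN
# output projects to the VTA, which is not simulated and is represented
# only by the dopamine level).  Stimulus intervals (uA/cm^2, uniform,
# redrawn every step inside the 500-3500 ms window) are tuned to the
# demo firing classes and marked as assumptions.
populations:
  - name: mpfc_pyr
    region: mPFC
    kind: PYR
    count: 16
    stimulus: [0.0, 7.0]
  - name: mpfc_pv
    region: mPFC
    kind: PV
    count: 2
    stimulus: [0.0, 1.5]
  - name: mpfc_cb
    region: mPFC
    kind: CB
    count: 2
    stimulus: [0.0, 4.0]
  - name: nac_msn
    region: NAc
    kind: MSN
    count: 4
    stimulus: [0.0, 180.0]
  - name: nac_pv
    region: NAc
    kind: PV
    count: 2
    stimulus: [0.0, 3.0]
  - name: nac_cb
    region: NAc
    kind: CB
    count: 2
    stimulus: [0.0, 3.0]
edges:
  - {pre: mpfc_pyr, post: mpfc_pv,  receptors: [AMPA, NMDA], target: soma}
  - {pre: mpfc_pyr, post: mpfc_cb,  receptors: [AMPA, NMDA], target: soma}
  - {pre: mpfc_pyr, post: nac_msn,  receptors: [AMPA, NMDA], target: spine,
     g_max: {AMPA: 0.2, NMDA: 0.08}}
  - {pre: mpfc_pyr, post: nac_pv,   receptors: [AMPA, NMDA], target: soma}
  - {pre: mpfc_pyr, post: nac_cb,   receptors: [AMPA, NMDA], target: soma}
  - {pre: mpfc_pv,  post: mpfc_pyr, receptors: [GABAa], target: soma,
     g_max: {GABAa: 0.8}}
  - {pre: mpfc_cb,  post: mpfc_pyr, receptors: [GABAa], target: soma,
     g_max: {GABAa: 0.8}}
  - {pre: nac_pv,   post: nac_msn,  receptors: [GABAa], target: soma,
     g_max: {GABAa: 0.08}}
  - {pre: nac_cb,   post: nac_msn,  receptors: [GABAa], target: soma,
     g_max: {GABAa: 0.08}}
receptors:        # Destexhe-type kinetic constants
  AMPA:  {g_max: 0.1,  e_rev: 0,   alpha: 1.1,   beta: 0.19,
          t_max: 1, v_p: 2, k_p: 5}
  NMDA:  {g_max: 0.05, e_rev: 0,   alpha: 0.072, beta: 0.0066,
          t_max: 1, v_p: 2, k_p: 5}
  GABAa: {g_max: 0.2,  e_rev: -80, alpha: 5,     beta: 0.18,
          t_max: 1, v_p: 2, k_p: 5}
stimulus_window: [500, 3500]
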