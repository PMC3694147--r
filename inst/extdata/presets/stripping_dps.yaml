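# Inert-gas stripping of dipropyl sulfide with stepped E/N: the analyte
# concentration decays exponentially while the drift voltage steps from
# 400 to 600 V; fragment branching rises with E/N.  A contaminant channel
# (constant source, independent of the analyte) is included as a negative
# control for slope confirmation.  Low analyte: no primary-ion depletion.
name: stripping_dps
extends: dps
stripping:
  m0_cm3: 1.0e+11
  tau_cycles: 60.0
  final_flux_boost: 3.0
en_schedule:
  voltages_v: [400.0, 450.0, 500.0, 550.0, 600.0]
  cycles_per_step: 5
branching_en:
  - tag: fragment
    en_td: [90.0, 150.0]
    branching: [0.01, 0.05]
  - tag: fragment_w
    en_td: [90.0, 150.0]
    branching: [0.01, 0.05]
  - tag: dehydrogenation
    en_td: [90.0, 150.0]
    branching: [5.0e-03, 0.02]
  - tag: dehydrogenation_w
    en_td: [90.0, 150.0]
    branching: [5.0e-03, 0.02]
contaminant:
  mz: 45
  cps: 500.0
monitor: [21, 32, 43, 45, 117, 118, 119, 120, 121]
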