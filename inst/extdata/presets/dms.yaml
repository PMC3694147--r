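# Dimethyl sulfide PIDK scenario: deep primary-ion depletion followed by
# replenishment under quasi-logarithmic headspace dilution.
name: dms
analyte: M
parent_species: MH+
parent_mz: 63
primary_mz: 21
conditions:
  pressure_mbar: 2.1
  temperature_k: 333.15
  voltage_v: 600.0
  length_cm: 9.2
  reaction_time_s: 1.0e-04
dilution:
  m0_cm3: 5.0e+14      # k_PT * M0 * t_r = 100: deep depletion at the start
  tau_cycles: 15.0
  n_cycles: 200
ions_cm3:
  H3O+: 1.0e+04        # x gain 300 = 3.0e6 cps primary-ion regime
  W1H+: 1.5e+03
  W2H+: 3.0e+02
  O2+: 5.0e+00
neutrals_cm3:
  H2O: 1.0e+12
  M: 0.0
gain_cps_per_cm3: 300.0
dwell_s: 0.5
monitor: [21, 32, 37, 47, 55, 61, 62, 63, 64, 65]
background_cps:
  default: 2.0
overlaps:
  - {mz: 47, source: W1H+, fraction: 2.0e-03}
  - {mz: 61, source: W2H+, fraction: 2.0e-03}
transmission:
  - {mz: 10.0,  coefficient: 0.15}
  - {mz: 50.0,  coefficient: 0.34}
  - {mz: 100.0, coefficient: 0.55}
  - {mz: 150.0, coefficient: 0.74}
  - {mz: 200.0, coefficient: 0.90}
  - {mz: 250.0, coefficient: 1.00}
mechanism1: false
mechanism2: false
soft: {z_th: 0.5, beta_cold: 0.0}
species:
  - {name: H3O+, mz: 19, role: primary-ion, pa: 691.0, formula: H3O}
  - {name: W1H+, mz: 37, role: parasitic-ion, pa: 808.0, formula: H5O2}
  - {name: W2H+, mz: 55, role: parasitic-ion, pa: 862.0, formula: H7O3}
  - {name: O2+, mz: 32, role: parasitic-ion, formula: O2}
  - {name: MH+, mz: 63, role: product-ion, formula: C2H7S}
  - {name: M+, mz: 62, role: product-ion, formula: C2H6S}
  - {name: D+, mz: 61, role: fragment-ion, formula: C2H5S}
  - {name: F1H+, mz: 47, role: fragment-ion, formula: CH3S}
  - {name: M, mz: 0, role: neutral, pa: 830.9, formula: C2H6S}
  - {name: H2O, mz: 0, role: neutral, pa: 691.0, formula: H2O}
  - {name: F1, mz: 0, role: neutral, pa: 759.7, formula: CH2S}
  - {name: CH4, mz: 0, role: neutral, formula: CH4}
  - {name: H2, mz: 0, role: neutral, formula: H2}
  - {name: O2, mz: 0, role: neutral, formula: O2}
reactions:
  # protonation with fragment / dehydrogenation branching
  - {reactants: {H3O+: 1, M: 1}, products: {MH+: 1, H2O: 1},
     k: 2.0e-09, branching: 0.965, intact: true}
  - {reactants: {H3O+: 1, M: 1}, products: {F1H+: 1, CH4: 1, H2O: 1},
     k: 2.0e-09, branching: 0.02, soft: true, tag: fragment}
  - {reactants: {H3O+: 1, M: 1}, products: {D+: 1, H2: 1, H2O: 1},
     k: 2.0e-09, branching: 0.015, soft: true, tag: dehydrogenation}
  # proton transfer from the water clusters
  - {reactants: {W1H+: 1, M: 1}, products: {MH+: 1, H2O: 2},
     k: 3.0e-09, branching: 0.965, intact: true}
  - {reactants: {W1H+: 1, M: 1}, products: {F1H+: 1, CH4: 1, H2O: 2},
     k: 3.0e-09, branching: 0.02, tag: fragment_w}
  - {reactants: {W1H+: 1, M: 1}, products: {D+: 1, H2: 1, H2O: 2},
     k: 3.0e-09, branching: 0.015, tag: dehydrogenation_w}
  - {reactants: {W2H+: 1, M: 1}, products: {MH+: 1, H2O: 3},
     k: 3.0e-09, branching: 0.965, intact: true}
  - {reactants: {W2H+: 1, M: 1}, products: {F1H+: 1, CH4: 1, H2O: 3},
     k: 3.0e-09, branching: 0.02, tag: fragment_w}
  - {reactants: {W2H+: 1, M: 1}, products: {D+: 1, H2: 1, H2O: 3},
     k: 3.0e-09, branching: 0.015, tag: dehydrogenation_w}
  # charge transfer from O2+
  - {reactants: {O2+: 1, M: 1}, products: {M+: 1, O2: 1}, k: 1.0e-10}
  # reversible water-cluster ladder (association effective bimolecular,
  # buffer stabilization folded in; dissociation in s^-1)
  - {reactants: {H3O+: 1, H2O: 1}, products: {W1H+: 1}, k: 1.0e-09}
  - {reactants: {W1H+: 1}, products: {H3O+: 1, H2O: 1}, k: 5.0e+03}
  - {reactants: {W1H+: 1, H2O: 1}, products: {W2H+: 1}, k: 5.0e-10}
  - {reactants: {W2H+: 1}, products: {W1H+: 1, H2O: 1}, k: 5.0e+03}
  # secondary proton transfer from the fragment (mechanism 1)
  - {reactants: {F1H+: 1, M: 1}, products: {MH+: 1, F1: 1},
     k: 8.0e-08, pa_gated: true, pa_donor: F1, pa_acceptor: M,
     tag: secondary}
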