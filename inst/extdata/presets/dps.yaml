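# Dipropyl sulfide PIDK scenario.  Besides the carbon-chain fragment
# (m/z 43) and dehydrogenation (m/z 117), an effective termolecular
# channel on the hydrated hydronium reagent forms weakly bound adducts at
# m/z 161 / 159, second order in the analyte.  The adducts are
# collisionally dissociated in the drift field (only those formed near
# the tube exit survive), and under deep depletion the cluster reagent
# never reaches the exit, so the adduct channels show the characteristic
# minimum under depletion and concentration peak during primary-ion
# replenishment, with clean order-2 kinetics in the normal phase.
name: dps
analyte: M
parent_species: MH+
parent_mz: 119
primary_mz: 21
conditions:
  pressure_mbar: 2.1
  temperature_k: 333.15
  voltage_v: 600.0
  length_cm: 9.2
  reaction_time_s: 1.0e-04
dilution:
  m0_cm3: 5.0e+14
  tau_cycles: 15.0
  n_cycles: 200
ions_cm3:
  H3O+: 1.0e+04
  W1H+: 1.5e+03
  W2H+: 3.0e+02
  O2+: 5.0e+00
neutrals_cm3:
  H2O: 1.0e+12
  M: 0.0
gain_cps_per_cm3: 300.0
dwell_s: 0.5
monitor: [21, 32, 37, 43, 55, 117, 118, 119, 120, 121, 159, 161]
background_cps:
  default: 2.0
overlaps:
  - {mz: 43, source: W1H+, fraction: 1.0e-03}
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
  - {name: MH+, mz: 119, role: product-ion, formula: C6H15S}
  - {name: M+, mz: 118, role: product-ion, formula: C6H14S}
  - {name: D+, mz: 117, role: fragment-ion, formula: C6H13S}
  - {name: F1H+, mz: 43, role: fragment-ion, formula: C3H7}
  - {name: AH+, mz: 161, role: adduct-ion, formula: C9H21S}
  - {name: A2H+, mz: 159, role: adduct-ion, formula: C9H19S}
  - {name: M, mz: 0, role: neutral, pa: 865.0, formula: C6H14S}
  - {name: H2O, mz: 0, role: neutral, pa: 691.0, formula: H2O}
  - {name: C3H8S, mz: 0, role: neutral, formula: C3H8S}
  - {name: C3H6, mz: 0, role: neutral, pa: 751.6, formula: C3H6}
  - {name: C3H4, mz: 0, role: neutral, formula: C3H4}
  - {name: H2, mz: 0, role: neutral, formula: H2}
  - {name: O2, mz: 0, role: neutral, formula: O2}
reactions:
  - {reactants: {H3O+: 1, M: 1}, products: {MH+: 1, H2O: 1},
     k: 2.0e-09, branching: 0.96, intact: true}
  - {reactants: {H3O+: 1, M: 1}, products: {F1H+: 1, C3H8S: 1, H2O: 1},
     k: 2.0e-09, branching: 0.03, soft: true, tag: fragment}
  - {reactants: {H3O+: 1, M: 1}, products: {D+: 1, H2: 1, H2O: 1},
     k: 2.0e-09, branching: 0.01, soft: true, tag: dehydrogenation}
  # effective termolecular adduct formation on the hydrated hydronium
  # reagent, second order in M
  - {reactants: {W1H+: 1, M: 2},
     products: {AH+: 1, C3H8S: 1, H2O: 2},
     k: 2.0e-21, branching: 0.7, tag: adduct}
  - {reactants: {W1H+: 1, M: 2},
     products: {A2H+: 1, H2: 1, C3H8S: 1, H2O: 2},
     k: 2.0e-21, branching: 0.3, tag: adduct}
  # collision-induced dissociation of the weakly bound adducts in the
  # drift field: only adducts formed near the tube exit survive
  - {reactants: {AH+: 1}, products: {MH+: 1, C3H6: 1},
     k: 1.2e+05, tag: adduct_cid}
  - {reactants: {A2H+: 1}, products: {MH+: 1, C3H4: 1},
     k: 1.2e+05, tag: adduct_cid}
  - {reactants: {W1H+: 1, M: 1}, products: {MH+: 1, H2O: 2},
     k: 3.0e-09, branching: 0.96, intact: true}
  - {reactants: {W1H+: 1, M: 1}, products: {F1H+: 1, C3H8S: 1, H2O: 2},
     k: 3.0e-09, branching: 0.03, tag: fragment_w}
  - {reactants: {W1H+: 1, M: 1}, products: {D+: 1, H2: 1, H2O: 2},
     k: 3.0e-09, branching: 0.01, tag: dehydrogenation_w}
  - {reactants: {W2H+: 1, M: 1}, products: {MH+: 1, H2O: 3},
     k: 3.0e-09, branching: 0.96, intact: true}
  - {reactants: {W2H+: 1, M: 1}, products: {F1H+: 1, C3H8S: 1, H2O: 3},
     k: 3.0e-09, branching: 0.03, tag: fragment_w}
  - {reactants: {W2H+: 1, M: 1}, products: {D+: 1, H2: 1, H2O: 3},
     k: 3.0e-09, branching: 0.01, tag: dehydrogenation_w}
  - {reactants: {O2+: 1, M: 1}, products: {M+: 1, O2: 1}, k: 1.0e-10}
  - {reactants: {H3O+: 1, H2O: 1}, products: {W1H+: 1}, k: 1.0e-09}
  - {reactants: {W1H+: 1}, products: {H3O+: 1, H2O: 1}, k: 5.0e+03}
  - {reactants: {W1H+: 1, H2O: 1}, products: {W2H+: 1}, k: 5.0e-10}
  - {reactants: {W2H+: 1}, products: {W1H+: 1, H2O: 1}, k: 5.0e+03}
  - {reactants: {F1H+: 1, M: 1}, products: {MH+: 1, C3H6: 1},
     k: 8.0e-08, pa_gated: true, pa_donor: C3H6, pa_acceptor: M,
     tag: secondary}
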