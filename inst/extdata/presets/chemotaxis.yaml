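name: chemotaxis
description: >
  Dictyostelium-style PIP2/PIP3 polarization under uniform cAMP
  stimulation with receptor adaptation.  Identification: X* = PIP3,
  X0 = PIP2, A = PI3K, B = PTEN, receptor = cAMP receptor.  All values
  chosen to sit inside the regime the scenario requires (rest state in
  the unactivated-rich phase, monostable-high excursion at stimulus
  onset, deep bistable quench at the adapted plateau so node-scale
  germs nucleate).
parameters:
  k_cat_A: {value: 2.0, unit: "1/s", provenance: assumed}
  k_cat_B: {value: 2.0, unit: "1/s", provenance: assumed}
  K_A: {value: 60.0, unit: "molecules/um^2", provenance: assumed}
  K_B: {value: 60.0, unit: "molecules/um^2", provenance: assumed}
  k_on_R: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_X: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_B: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_off_AR: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_AX: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_B: {value: 1.0, unit: "1/s", provenance: assumed}
  A_tot: {value: 70000, unit: "molecules", provenance: assumed}
  B_tot: {value: 60000, unit: "molecules", provenance: assumed}
  X_tot: {value: 600, unit: "molecules/um^2", provenance: assumed}
  D: {value: 0.1, unit: "um^2/s", provenance: assumed}
  R: {value: 7.0, unit: "um", provenance: assumed}
signal:
  type: adapting
  sigma_on: {value: 0.20, unit: "dimensionless", provenance: assumed}
  t_on: {value: 5.0, unit: "s", provenance: assumed}
  tau: {value: 8.0, unit: "s", provenance: assumed}
  plateau_fraction: {value: 0.15, unit: "dimensionless", provenance: assumed}
scenario:
  engine: meanfield
  mesh_level: {value: 4, unit: "subdivisions", provenance: assumed}
  t_end: {value: 350, unit: "s", provenance: assumed}
  snapshot_dt: {value: 5, unit: "s", provenance: assumed}
  noise_rate: {value: 0.02, unit: "1/s", provenance: assumed}
  init_noise_rel: {value: 0.05, unit: "dimensionless", provenance: assumed}
  noise_phi_set: {value: 1.0, unit: "dimensionless", provenance: "assumed; fluctuation amplitude of the activated phase"}
  var_lo: {value: 0.001, unit: "dimensionless", provenance: assumed}
  var_hi: {value: 0.02, unit: "dimensionless", provenance: assumed}
  rtol: {value: 1.0e-5, unit: "dimensionless", provenance: assumed}
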