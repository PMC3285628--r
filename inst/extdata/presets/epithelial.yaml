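name: epithelial
description: >
  Apico-basal polarization of an epithelial cell.  Identification:
  X* = PIP3, X0 = PIP2, A = PI3K (recruited by activated cadherins and
  integrins, modelled as a constant uniform receptor field), B = PTEN.
  The membrane starts uniformly PIP3-rich; a PIP2-rich germ placed by an
  active process (heterogeneous nucleation) either dissolves or triggers
  polarization depending on its radius.  Totals are balanced so the
  polarized equilibrium is near half-and-half (quasi-equatorial
  interface).
parameters:
  k_cat_A: {value: 0.45, unit: "1/s", provenance: assumed}
  k_cat_B: {value: 0.45, unit: "1/s", provenance: assumed}
  K_A: {value: 60.0, unit: "molecules/um^2", provenance: assumed}
  K_B: {value: 60.0, unit: "molecules/um^2", provenance: assumed}
  k_on_R: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_X: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_B: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_off_AR: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_AX: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_B: {value: 1.0, unit: "1/s", provenance: assumed}
  A_tot: {value: 60000, unit: "molecules", provenance: assumed}
  B_tot: {value: 60000, unit: "molecules", provenance: assumed}
  X_tot: {value: 600, unit: "molecules/um^2", provenance: assumed}
  D: {value: 0.12, unit: "um^2/s", provenance: assumed}
  R: {value: 5.0, unit: "um", provenance: assumed}
signal:
  type: constant
  sigma: {value: 0.05, unit: "dimensionless", provenance: assumed}
scenario:
  engine: meanfield
  mesh_level: {value: 3, unit: "subdivisions", provenance: assumed}
  t_end: {value: 700, unit: "s", provenance: assumed}
  rtol: {value: 1.0e-5, unit: "dimensionless", provenance: assumed}
  radius_min: {value: 0.4, unit: "um", provenance: assumed}
  radius_max: {value: 2.4, unit: "um", provenance: assumed}
  radius_n: {value: 6, unit: "count", provenance: assumed}
  polarized_var: {value: 0.05, unit: "dimensionless", provenance: assumed}
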