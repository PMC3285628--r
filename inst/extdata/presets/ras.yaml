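name: ras
description: >
  Ras signaling domains in the inner plasma-membrane leaflet.
  Identification: X* = Ras-GTP, X0 = Ras-GDP, A = SOS-like GEF
  (allosterically recruited by Ras-GTP), B = Ras-GAP.  Two paired
  stochastic runs differ only in the GEF total: inside the bistable
  region a stable signaling domain persists; outside, only intermittent
  nanoclusters appear.
parameters:
  k_cat_A: {value: 2.0, unit: "1/s", provenance: assumed}
  k_cat_B: {value: 2.0, unit: "1/s", provenance: assumed}
  K_A: {value: 30.0, unit: "molecules/um^2", provenance: assumed}
  K_B: {value: 30.0, unit: "molecules/um^2", provenance: assumed}
  k_on_R: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_X: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_B: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_off_AR: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_AX: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_B: {value: 1.0, unit: "1/s", provenance: assumed}
  A_tot: {value: 4000, unit: "molecules", provenance: assumed}
  B_tot: {value: 2000, unit: "molecules", provenance: assumed}
  X_tot: {value: 300, unit: "molecules/um^2", provenance: assumed}
  D: {value: 0.1, unit: "um^2/s", provenance: assumed}
  R: {value: 2.0, unit: "um", provenance: assumed}
signal:
  type: constant
  sigma: {value: 0.01, unit: "dimensionless", provenance: "assumed; basal GEF recruitment"}
scenario:
  engine: ssa
  mesh_level: {value: 2, unit: "subdivisions", provenance: assumed}
  t_end: {value: 600, unit: "s", provenance: assumed}
  snapshot_dt: {value: 2, unit: "s", provenance: assumed}
  A_inside: {value: 4000, unit: "molecules", provenance: assumed}
  A_outside: {value: 600, unit: "molecules", provenance: assumed}
  phi_init: {value: 0.02, unit: "dimensionless", provenance: assumed}
  germ_radius: {value: 0.7, unit: "um", provenance: assumed}
  persistence_horizon: {value: 100, unit: "s", provenance: assumed}
  patch_threshold: {value: 0.5, unit: "dimensionless", provenance: assumed}
  min_patch_nodes: {value: 2, unit: "count", provenance: assumed}
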