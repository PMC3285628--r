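name: yeast
description: >
  Budding-yeast polarization.  Identification: X* = active Cdc42,
  X0 = inactive Cdc42, A = Cdc24 GEF (recruited by active Cdc42 via
  Bem1), B = GAP (Rga2-like).  A small constant basal recruitment of
  the GEF (through the receptor channel) stands in for spontaneous
  membrane association; the feedback-arm dissociation rate is
  pre-solved at run time so 10% of the GEF is membrane bound at the
  reference state.  The A_tot ladder corresponds to 1, 10 and 50 nM of
  GEF in the cytosolic volume.
parameters:
  k_cat_A: {value: 5.0, unit: "1/s", provenance: assumed}
  k_cat_B: {value: 5.0, unit: "1/s", provenance: assumed}
  K_A: {value: 20.0, unit: "molecules/um^2", provenance: assumed}
  K_B: {value: 20.0, unit: "molecules/um^2", provenance: assumed}
  k_on_R: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_X: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_on_B: {value: 0.012, unit: "um^3/s", provenance: assumed}
  k_off_AR: {value: 1.0, unit: "1/s", provenance: assumed}
  k_off_AX: {value: 13.0, unit: "1/s", provenance: "assumed; re-solved at run time for the bound-fraction target"}
  k_off_B: {value: 1.0, unit: "1/s", provenance: assumed}
  A_tot: {value: 1970, unit: "molecules", provenance: "assumed; 50 nM in V_cyt"}
  B_tot: {value: 370, unit: "molecules", provenance: assumed}
  X_tot: {value: 200, unit: "molecules/um^2", provenance: assumed}
  D: {value: 0.03, unit: "um^2/s", provenance: assumed}
  R: {value: 2.5, unit: "um", provenance: assumed}
signal:
  type: constant
  sigma: {value: 0.01, unit: "dimensionless", provenance: "assumed; basal GEF association"}
scenario:
  engine: ssa
  mesh_level: {value: 2, unit: "subdivisions", provenance: assumed}
  t_end: {value: 1200, unit: "s", provenance: assumed}
  snapshot_dt: {value: 4, unit: "s", provenance: assumed}
  A_low: {value: 40, unit: "molecules", provenance: "assumed; 1 nM"}
  A_mid: {value: 394, unit: "molecules", provenance: "assumed; 10 nM"}
  A_high: {value: 1970, unit: "molecules", provenance: "assumed; 50 nM"}
  phi_ref: {value: 0.5, unit: "dimensionless", provenance: assumed}
  bound_frac: {value: 0.1, unit: "dimensionless", provenance: assumed}
  phi_init: {value: 0.05, unit: "dimensionless", provenance: assumed}
  germ_radius: {value: 0.8, unit: "um", provenance: assumed}
  patch_threshold: {value: 0.5, unit: "dimensionless", provenance: assumed}
  min_flicker_nodes: {value: 1, unit: "count", provenance: "assumed; nanocluster scale"}
  min_cap_nodes: {value: 2, unit: "count", provenance: "assumed; polar-cap scale"}
  kcat_ladder: {value: 100.0, unit: "1/s", provenance: "assumed; large catalytic burst per binding in the low-copy limit"}
  k_on_X_ladder: {value: 0.0002, unit: "um^3/s", provenance: "assumed; slow-cycling feedback arm"}
  B_ladder: {value: 60, unit: "molecules", provenance: assumed}
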