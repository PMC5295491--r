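{
  "description": "Reduced single-aorta network: tapered ascending aorta, arch, proximal descending aorta, isthmus (repair-site target segment) and descending aorta. Head-and-arm vessels are lumped into one side windkessel at the distal arch junction; the descending aorta ends in a three-element windkessel. Defaults give control-like root pressures (about 115/70 mmHg) at a cardiac output near 5 L/min.",
  "cycle_period_s": 0.85,
  "p_ref_mmHg": 72,
  "p_init_mmHg": 95,
  "blood": { "rho_kg_m3": 1060, "mu_poise": 0.04 },
  "segments": [
    { "name": "ascending_aorta", "length_cm": 5.0, "inlet_diameter_cm": 2.6, "outlet_diameter_cm": 2.5, "distensibility_per_mmHg": 5.0e-3, "n_nodes": 16 },
    { "name": "aortic_arch", "length_cm": 4.5, "inlet_diameter_cm": 2.5, "outlet_diameter_cm": 2.3, "distensibility_per_mmHg": 5.0e-3, "n_nodes": 12 },
    { "name": "proximal_descending", "length_cm": 5.0, "inlet_diameter_cm": 2.2, "outlet_diameter_cm": 2.1, "distensibility_per_mmHg": 4.5e-3, "n_nodes": 12 },
    { "name": "isthmus", "length_cm": 2.5, "inlet_diameter_cm": 2.1, "outlet_diameter_cm": 2.0, "distensibility_per_mmHg": 4.5e-3, "n_nodes": 48 },
    { "name": "descending_aorta", "length_cm": 16.0, "inlet_diameter_cm": 2.0, "outlet_diameter_cm": 1.7, "distensibility_per_mmHg": 4.0e-3, "n_nodes": 24 }
  ],
  "heart": {
    "Emax_mmHg_ml": 2.5, "Emin_mmHg_ml": 0.08, "V0_ml": 10,
    "p_fill_mmHg": 10, "Rmv_mmHg_s_ml": 0.01, "Rav_mmHg_s_ml": 0.02,
    "t_rise_s": 0.30, "t_fall_s": 0.45
  },
  "junction_terminals": [
    null,
    { "R1_mmHg_s_ml": 0.10, "R2_mmHg_s_ml": 3.55, "C_ml_mmHg": 0.40, "p_ven_mmHg": 5 },
    null,
    null
  ],
  "terminal": { "R1_mmHg_s_ml": 0.17, "R2_mmHg_s_ml": 1.33, "C_ml_mmHg": 0.90, "p_ven_mmHg": 5 }
}
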