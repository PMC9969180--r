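{
  "description": "Default study conditions for broadband Mueller polarimetry of saccharide solutions at 20 C: fitted specific rotations at 589 nm (deg mL g^-1 dm^-1), glucose mutarotation kinetics, and instrument settings.",
  "glucose": {
    "molar_mass": 180.156,
    "specific_rotation_589": 52.68,
    "alpha_specific_rotation_589": 104.66,
    "beta_specific_rotation_589": 20.74,
    "tau_s": 2.332e-4,
    "K_printed": 1.777,
    "eq_alpha_fraction": 0.36,
    "default_concentration_M": 0.25
  },
  "fructose": {
    "molar_mass": 180.156,
    "specific_rotation_589": -92.53
  },
  "sucrose": {
    "molar_mass": 342.297,
    "specific_rotation_589": 65.36
  },
  "instrument": {
    "noise_floor": 0.001,
    "path_length_mm": 50.04,
    "temperature_C": 20,
    "wavelength_min_nm": 300,
    "wavelength_max_nm": 1000,
    "wavelength_step_nm": 1,
    "first_measurement_s": 300,
    "last_measurement_s": 43200,
    "n_time_points": 100
  }
}
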