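{
  "description": "Sellmeier coefficients of pure water at 20.0 C (Daimon & Masumura 2007 parameterization); n^2 = 1 + sum A_i L^2/(L^2 - B_i), L in nm, B_i in nm^2",
  "temperature_C": 20.0,
  "amplitudes": [0.5684027565, 0.1726177391, 0.02086189578, 0.1130748688],
  "resonances_nm2": [5101.829712, 18211.53936, 26207.22293, 10697927.21]
}
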