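# Nucletron mHDR-v2 Ir-192 source parameters (consensus-style values), v1.
# Units: energies keV, lengths mm unless noted, S_K in U = cGy cm^2 h^-1.
name: mHDR-v2
half_life_days: 73.83
air_kerma_strength_U: 32800
strength_date: 0
dose_rate_constant_cGy_per_hU: 1.109
active_length_mm: 3.5
capsule_length_mm: 4.5
diameter_mm: 0.9
# radial dose function g(r), r in cm, 5th-order polynomial c0 + c1 r + ... + c5 r^5,
# renormalised so g(1 cm) = 1 exactly; valid 0.25-10 cm, clamped outside.
radial_dose_coeffs:
  - 0.987323192
  - 0.0225103966
  - -0.01207745843
  - 0.00248876793
  - -0.0002544608984
  - 0.000009562777597
radial_dose_r_range_cm: [0.25, 10.0]
# 1D anisotropy factor phi_an(r), constant default
anisotropy_factor: 0.98
# air-kerma rate constant, U per GBq
air_kerma_rate_constant_U_per_GBq: 110
# beta-particle plumbing: capsule transmits 3e-4 of decay electrons;
# escaped-beta dose fraction relative to gamma dose
capsule_beta_transmission: 3.0e-4
beta_dose_fraction: 5.0e-4
beta_endpoint_keV: 675
# principal gamma lines: energy (keV), intensity (photons per decay)
gamma_lines:
  - {energy: 205.79, intensity: 0.0334}
  - {energy: 295.96, intensity: 0.2872}
  - {energy: 308.46, intensity: 0.2968}
  - {energy: 316.51, intensity: 0.8286}
  - {energy: 468.07, intensity: 0.4781}
  - {energy: 484.58, intensity: 0.0319}
  - {energy: 588.58, intensity: 0.0452}
  - {energy: 604.41, intensity: 0.0820}
  - {energy: 612.46, intensity: 0.0534}
  - {energy: 884.54, intensity: 0.0291}
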