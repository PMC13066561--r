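{
  "desk_scale": false,
  "note": "Full-scale reference targets. Reproducing them requires the deposited chromatosome reference structure with multi-microsecond replica trajectories (contact percentages) or the underlying time-resolved intensity tables (rate constants); they are recorded here as machine-readable targets only, and the package's desk-scale surrogates are validated against the property suites and the sign-level toy experiment instead.",
  "rate_constants": [
    {"system": "nucleosome", "k_app_per_s": 4.3e-05, "uncertainty_per_s": 7.0e-08},
    {"system": "chromatosome", "k_app_per_s": 1.7e-05, "uncertainty_per_s": 4.1e-08},
    {"system": "h4_tetra_acetylated_chromatosome", "k_app_per_s": 4.5e-06, "uncertainty_per_s": 5.8e-08},
    {"system": "nucleosome_core_particle", "k_app_per_s": 6.9e-06, "uncertainty_per_s": 3.8e-07}
  ],
  "contact_percentages": [
    {"tail": "H3_distal", "region": "core", "condition": "unmodified", "percent": 90},
    {"tail": "H3_distal", "region": "core", "condition": "h4_tetra_acetylated", "percent": 75},
    {"tail": "H3_proximal", "region": "core", "condition": "unmodified", "percent": 64},
    {"tail": "H3_proximal", "region": "core", "condition": "h4_tetra_acetylated", "percent": 57},
    {"tail": "H3_proximal", "region": "linker", "condition": "unmodified", "percent": 21},
    {"tail": "H3_proximal", "region": "linker", "condition": "h4_tetra_acetylated", "percent": 13}
  ]
}
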