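{
  "version": "1.0",
  "note": "Published AICc model-ranking columns for the three candidate sets (insect traits, host traits, insect evolutionary history). K is the number of estimated parameters.",
  "insect_traits": [
    {"model": "voltinism", "K": 2, "AICc": 43.308},
    {"model": "voltinism + reproductive_strategy + dispersal", "K": 5, "AICc": 43.911},
    {"model": "reproductive_strategy", "K": 2, "AICc": 44.475},
    {"model": "null", "K": 1, "AICc": 44.794},
    {"model": "congener", "K": 2, "AICc": 46.073},
    {"model": "n_native_host_genera", "K": 2, "AICc": 46.305},
    {"model": "pest_status", "K": 2, "AICc": 46.733},
    {"model": "dispersal", "K": 2, "AICc": 46.791},
    {"model": "native_range", "K": 3, "AICc": 48.339},
    {"model": "guild", "K": 4, "AICc": 50.651},
    {"model": "native_range + pest_status + n_native_host_genera", "K": 5, "AICc": 51.935},
    {"model": "global", "K": 11, "AICc": 64.639}
  ],
  "host_traits": [
    {"model": "shade_tolerance + drought_tolerance", "K": 6, "AICc": 109.547},
    {"model": "growth_rate", "K": 3, "AICc": 114.765},
    {"model": "wood_density + growth_rate", "K": 4, "AICc": 114.929},
    {"model": "wood_density", "K": 2, "AICc": 115.567},
    {"model": "null", "K": 1, "AICc": 116.849},
    {"model": "foliage_texture + growth_rate", "K": 5, "AICc": 116.863},
    {"model": "foliage_texture", "K": 3, "AICc": 118.605},
    {"model": "drought_tolerance", "K": 4, "AICc": 119.142},
    {"model": "global", "K": 14, "AICc": 121.842},
    {"model": "fire_tolerance + drought_tolerance", "K": 7, "AICc": 124.834}
  ],
  "insect_evolution": [
    {"model": "shared_genus", "K": 2, "AICc": 98.778},
    {"model": "null", "K": 1, "AICc": 103.908},
    {"model": "shared_family", "K": 2, "AICc": 104.958}
  ]
}
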