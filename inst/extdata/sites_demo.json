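{
  "note": "Synthetic demo site context for German coastal monitoring stations: mean mussel water content and breathing-water fraction of sample wet weight per site, plus the matrix class of each monitored species/tissue.",
  "sites": {
    "NS1": {"water_fraction": 0.906, "breathing_water_fraction": 0.67},
    "NS2": {"water_fraction": 0.926, "breathing_water_fraction": 0.58},
    "BS":  {"water_fraction": 0.947, "breathing_water_fraction": 0.67}
  },
  "matrix_classes": {
    "Mytilus edulis/soft body": "bivalve",
    "Zoarces viviparus/fillet": "fish_muscle"
  }
}
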