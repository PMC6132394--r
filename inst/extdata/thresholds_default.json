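{
  "note": "Default regulatory reference values. Food maximum levels (kind=ML) are transcribed from Regulation (EC) No 1881/2006 as amended (Reg. 629/2008, 835/2011, 1259/2011) and are externally sourced reference data; EQS/EAC/national values follow the WFD EQS Directive 2013/39/EU, OSPAR agreement 2004-15 and the Norwegian quality standard.",
  "thresholds": [
    {"analyte": "Pb", "matrix_class": "bivalve", "value": 1.5, "unit": "mg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EC) No 1881/2006, point 3.1.11 (bivalve molluscs)"},
    {"analyte": "Pb", "matrix_class": "fish_muscle", "value": 0.30, "unit": "mg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EC) No 1881/2006, point 3.1.5 (muscle meat of fish)"},
    {"analyte": "Cd", "matrix_class": "bivalve", "value": 1.0, "unit": "mg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EC) No 1881/2006, point 3.2.16 (bivalve molluscs)"},
    {"analyte": "Cd", "matrix_class": "fish_muscle", "value": 0.050, "unit": "mg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EC) No 1881/2006, point 3.2.9 (muscle meat of fish)"},
    {"analyte": "Hg", "matrix_class": "bivalve", "value": 0.50, "unit": "mg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EC) No 1881/2006, point 3.3.1 (fishery products)"},
    {"analyte": "Hg", "matrix_class": "fish_muscle", "value": 0.50, "unit": "mg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EC) No 1881/2006, point 3.3.1 (muscle meat of fish)"},
    {"analyte": "B[a]P", "matrix_class": "bivalve", "value": 5.0, "unit": "µg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 835/2011, point 6.1.5 (bivalve molluscs)"},
    {"analyte": "Sum4PAH", "matrix_class": "bivalve", "value": 30.0, "unit": "µg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 835/2011, point 6.1.5 (sum of B[a]P, B[a]A, B[b]F, chrysene)"},
    {"analyte": "PCDDF-TEQ", "matrix_class": "fish_muscle", "value": 3.5, "unit": "pg/g", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 1259/2011, point 5.3 (sum of dioxins, WHO-TEQ)"},
    {"analyte": "PCDDF-dlPCB-TEQ", "matrix_class": "fish_muscle", "value": 6.5, "unit": "pg/g", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 1259/2011, point 5.3 (sum of dioxins and dl-PCBs, WHO-TEQ)"},
    {"analyte": "PCDDF-dlPCB-TEQ", "matrix_class": "bivalve", "value": 6.5, "unit": "pg/g", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 1259/2011, point 5.3 (fishery products incl. bivalves)"},
    {"analyte": "Sum6PCB", "matrix_class": "fish_muscle", "value": 75.0, "unit": "µg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 1259/2011, point 5.3 (sum of 6 indicator ndl-PCBs)"},
    {"analyte": "Sum6PCB", "matrix_class": "bivalve", "value": 75.0, "unit": "µg/kg", "basis": "wet", "kind": "ML", "protection_goal": "human_health", "source": "Reg. (EU) No 1259/2011, point 5.3 (fishery products incl. bivalves)"},
    {"analyte": "PFOS", "matrix_class": "fish_muscle", "value": 9.1, "unit": "µg/kg", "basis": "wet", "kind": "EQS", "protection_goal": "human_health", "source": "Directive 2013/39/EU (biota EQS, fish)"},
    {"analyte": "PBDE", "matrix_class": "fish_muscle", "value": 0.0085, "unit": "µg/kg", "basis": "wet", "kind": "EQS", "protection_goal": "human_health", "source": "Directive 2013/39/EU (biota EQS, sum BDE-28,-47,-99,-100,-153,-154)"},
    {"analyte": "HBCDD", "matrix_class": "fish_muscle", "value": 167.0, "unit": "µg/kg", "basis": "wet", "kind": "EQS", "protection_goal": "secondary_poisoning", "source": "Directive 2013/39/EU (biota EQS, sum of alpha/beta/gamma-HBCDD)"},
    {"analyte": "HBCDD", "matrix_class": "fish_muscle", "value": 6100.0, "unit": "µg/kg", "basis": "wet", "kind": "national_QS", "protection_goal": "human_health", "source": "EQS dossier HBCDD (human-health quality standard)"},
    {"analyte": "TBT", "matrix_class": "bivalve", "value": 12.0, "unit": "µg/kg", "basis": "dry", "kind": "EAC", "protection_goal": "secondary_poisoning", "source": "OSPAR agreement 2004-15 (EAC for TBT in bivalves)"},
    {"analyte": "TBT", "matrix_class": "bivalve", "value": 150.0, "unit": "µg/kg", "basis": "wet", "kind": "national_QS", "protection_goal": "ecotoxicity", "source": "Norwegian Environment Agency biota quality standard for TBT compounds"}
  ]
}
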