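{
  "prefix": "NWKI",
  "labelPredicate": "http://www.w3.org/2000/01/rdf-schema#label",
  "typePredicate": "https://example.org/nanowiki#materialType",
  "citationPredicate": "http://purl.org/dc/terms/source",
  "measurements": {
    "https://example.org/nanowiki#primaryParticleSize": {
      "endpoint": "particle size",
      "topcategory": "P-CHEM",
      "category": "PC_GRANULOMETRY_SECTION",
      "unit": "nm"
    },
    "https://example.org/nanowiki#zetaPotential": {
      "endpoint": "zeta potential",
      "topcategory": "P-CHEM",
      "category": "ZETA_POTENTIAL_SECTION",
      "unit": "mV"
    },
    "https://example.org/nanowiki#cellViability": {
      "endpoint": "percentage viable cells",
      "topcategory": "TOX",
      "category": "TO_CYTOTOXICITY_SECTION",
      "unit": "%"
    }
  }
}
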