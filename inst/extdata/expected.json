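{
  "diabetes_matrix": [
    {
      "stage": "stage1",
      "proposal": "metformin",
      "conforms": true,
      "text": ""
    },
    {
      "stage": "stage1",
      "proposal": "agi",
      "conforms": false,
      "text": "AGI should be prescribed only as second-line treatment. Guideline recommends metformin as first-line treatment."
    },
    {
      "stage": "stage1",
      "proposal": "other",
      "conforms": false,
      "text": "Sulfonamides, glinides and glitazones are not recommended. Guideline recommends metformin as first-line treatment."
    },
    {
      "stage": "stage2",
      "proposal": "metformin",
      "conforms": true,
      "text": ""
    },
    {
      "stage": "stage2",
      "proposal": "agi",
      "conforms": true,
      "text": ""
    },
    {
      "stage": "stage2",
      "proposal": "other",
      "conforms": false,
      "text": "Sulfonamides, glinides and glitazones are not recommended. Guideline recommends metformin as first-line treatment, and AGI as second-line."
    }
  ],
  "statin_labels": [
    {
      "age": 60,
      "prevention": "primary",
      "history": "none",
      "label": "diet_simvastatin, diet_pravastatin, diet_atorvastatin"
    },
    {
      "age": 85,
      "prevention": "primary",
      "history": "none",
      "label": "no treatment"
    },
    {
      "age": 60,
      "prevention": "secondary",
      "history": "none",
      "label": "diet_simvastatin, diet_pravastatin, diet_atorvastatin"
    },
    {
      "age": 85,
      "prevention": "secondary",
      "history": "none",
      "label": "diet_simvastatin, diet_pravastatin, diet_atorvastatin"
    },
    {
      "age": 60,
      "prevention": "primary",
      "history": "statins_failed",
      "label": "[diet_rosuvastatin]"
    },
    {
      "age": 85,
      "prevention": "primary",
      "history": "statins_failed",
      "label": "no treatment"
    },
    {
      "age": 60,
      "prevention": "secondary",
      "history": "statins_failed",
      "label": "[diet_rosuvastatin]"
    },
    {
      "age": 85,
      "prevention": "secondary",
      "history": "statins_failed",
      "label": "[diet_rosuvastatin]"
    }
  ]
}
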