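# Type 2 diabetes, oral monotherapy: metformin first-line, alpha-glucosidase
# inhibitor (AGI) second-line, while glycated haemoglobin is <= 6.5%.
name: diabetes-type2-monotherapy
drug_classes:
  metformin: [A10BA]
  alpha_glucosidase_inhibitor: [A10BF]
  sulfonamide: [A10BB]
  glinide: [A10BX02, A10BX03]   # no single ATC code covers the glinides
  glitazone: [A10BG]
  oral_antidiabetic: [A10B]
attributes:
  hba1c: {type: numeric, grid: [6.0, 7.0]}
treatments:
  diet_metformin:
    components:
      - non_drug: diet
      - drug: {atc: A10BA02, inn: metformin, dose: {value: 500, unit: mg, per: day}}
  diet_agi:
    components:
      - non_drug: diet
      - drug: {atc: A10BF01, inn: acarbose, dose: {value: 100, unit: mg, per: day}}
recommendations:
  - id: monotherapy
    type: should_prescribe
    conditions:
      and:
        - therapeutic:
            status: [proposed]
            components:
              - non_drug: diet
              - class: oral_antidiabetic
        - clinical: {attribute: hba1c, op: "<=", value: 6.5}
    lines:
      - - components: [{non_drug: diet}, {class: metformin}]
      - - components: [{non_drug: diet}, {class: alpha_glucosidase_inhibitor}]
    explanation_labels:
      - ""
      - "AGI should be prescribed only as second-line treatment."
      - "Sulfonamides, glinides and glitazones are not recommended."
    advice_labels:
      - "Guideline recommends metformin as first-line treatment."
      - "Guideline recommends metformin as first-line treatment, and AGI as second-line."
    reference_label: ""
generics:
  applicability:
    "1": not_applicable
    "2": not_applicable
    "3": not_applicable
    "4": not_applicable
    "5": full
    "6": partial   # per pharmaco-therapeutic class; the oral_antidiabetic
    "7": full      # umbrella is a query class, not a pharmaco-therapeutic one
    "8": not_applicable
  scope:
    "6": [metformin, alpha_glucosidase_inhibitor, sulfonamide, glinide, glitazone]
indications:
  - {class: oral_antidiabetic, indication: type2_diabetes}
verification:
  attributes: [hba1c]
  dose_grid:
    - {value: 500, unit: mg, per: day}
    - {value: 100, unit: mg, per: day}
  history_scenarios:
    none: []
    metformin_failed:
      - components:
          - non_drug: diet
          - drug: {atc: A10BA02, inn: metformin, dose: {value: 500, unit: mg, per: day}}
        status: past
        efficacy: ineffective
        start: 2024-02-01
        end: 2025-02-01
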