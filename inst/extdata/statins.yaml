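# Dyslipidaemia fragment: no lipid-lowering drug treatment above 80 years in
# primary prevention; simvastatin, pravastatin or atorvastatin (with diet) as
# first-line drug treatment; rosuvastatin only after tolerance or efficacy
# problems with the other statins.
name: dyslipidaemia-statins
drug_classes:
  simvastatin: [C10AA01]
  pravastatin: [C10AA03]
  atorvastatin: [C10AA05]
  rosuvastatin: [C10AA07]
  statin: [C10AA]
attributes:
  age: {type: numeric, grid: [60, 85]}
  prevention: {type: categorical, grid: [primary, secondary]}
treatments:
  diet_simvastatin:
    components:
      - non_drug: diet
      - drug: {atc: C10AA01, inn: simvastatin, dose: {value: 20, unit: mg, per: day}}
  diet_pravastatin:
    components:
      - non_drug: diet
      - drug: {atc: C10AA03, inn: pravastatin, dose: {value: 40, unit: mg, per: day}}
  diet_atorvastatin:
    components:
      - non_drug: diet
      - drug: {atc: C10AA05, inn: atorvastatin, dose: {value: 10, unit: mg, per: day}}
  diet_rosuvastatin:
    components:
      - non_drug: diet
      - drug: {atc: C10AA07, inn: rosuvastatin, dose: {value: 5, unit: mg, per: day}}
recommendations:
  - id: no_start_over_80_primary
    type: should_not_prescribe
    conditions:
      and:
        - clinical: {attribute: age, op: ">", value: 80}
        - clinical: {attribute: prevention, op: "=", value: primary}
    pattern:
      status: [proposed]
      components:
        - class: statin
        - any: {}
    criticism_label: "It is not recommended to start a lipid-lowering drug treatment for patients older than 80 in primary prevention."
  - id: statin_choice
    type: should_prescribe
    lines:
      - - components: [{non_drug: diet}, {class: simvastatin}]
        - components: [{non_drug: diet}, {class: pravastatin}]
        - components: [{non_drug: diet}, {class: atorvastatin}]
      - - components: [{non_drug: diet}, {class: rosuvastatin}]
    explanation_labels:
      - ""
      - "Rosuvastatin should only be used in case of tolerance or efficacy problems with other statins."
      - "Only statins are recommended as lipid-lowering drug treatment."
    advice_labels:
      - "Guideline recommends simvastatin, pravastatin or atorvastatin as first-line treatment."
      - "Guideline recommends rosuvastatin as second-line treatment."
    reference_label: ""
generics:
  applicability:
    "1": not_applicable
    "2": not_applicable
    "3": not_applicable
    "4": not_applicable
    "5": full
    "6": not_applicable
    "7": full
    "8": not_applicable
indications:
  - {class: statin, indication: dyslipidaemia}
verification:
  attributes: [age, prevention]
  dose_grid:
    - {value: 20, unit: mg, per: day}
  history_scenarios:
    none: []
    statins_failed:
      - components:
          - non_drug: diet
          - drug: {atc: C10AA01, inn: simvastatin, dose: {value: 20, unit: mg, per: day}}
        status: past
        efficacy: ineffective
        start: 2023-09-01
        end: 2024-03-01
      - components:
          - non_drug: diet
          - drug: {atc: C10AA03, inn: pravastatin, dose: {value: 40, unit: mg, per: day}}
        status: past
        efficacy: ineffective
        start: 2024-03-01
        end: 2024-09-01
      - components:
          - non_drug: diet
          - drug: {atc: C10AA05, inn: atorvastatin, dose: {value: 10, unit: mg, per: day}}
        status: past
        efficacy: ineffective
        start: 2024-09-01
        end: 2025-03-01
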