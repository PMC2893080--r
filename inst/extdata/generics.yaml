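# Generic-recommendation exercise base: a smoking-cessation-style treatment
# ladder plus classes chosen to exercise the generic rules — a multi-code
# glinide class, a beta-blocker class for the same-class-association rule,
# and a bupropion exception to dose lowering (narrow therapeutic range).
name: generic-exercise
drug_classes:
  nicotine_replacement: [N07BA01]
  bupropion: [N06AX12]
  beta_blocker: [C07AB]
  glinide: [A10BX02, A10BX03]
attributes:
  smoker: {type: categorical, grid: ["yes", "no"]}
treatments:
  nicotine_patch:
    components:
      - drug: {atc: N07BA01, inn: nicotine, dose: {value: 15, unit: mg, per: day}}
  bupropion_std:
    components:
      - drug: {atc: N06AX12, inn: bupropion, dose: {value: 300, unit: mg, per: day}}
recommendations:
  - id: cessation
    type: should_prescribe
    lines:
      - - components: [{class: nicotine_replacement}]
      - - components: [{class: bupropion}]
    explanation_labels:
      - ""
      - "Bupropion should be reserved for second-line use."
      - "Other drugs are not recommended for smoking cessation."
    advice_labels:
      - "Guideline recommends nicotine replacement as first-line treatment."
      - "Guideline recommends bupropion as second-line treatment."
    reference_label: ""
generics:
  applicability:
    "1": full
    "2": full
    "3": full
    "4": full
    "5": full
    "6": full
    "7": full
    "8": full
  exceptions:
    "4": [bupropion]
indications:
  - {class: nicotine_replacement, indication: tobacco_addiction}
  - {class: bupropion, indication: tobacco_addiction}
verification:
  attributes: [smoker]
  dose_grid:
    - {value: 15, unit: mg, per: day}
  history_scenarios:
    none: []
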