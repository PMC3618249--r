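domain gene
  states: low, normal, high
  kind: ordered
  default: normal
domain metabolite
  states: low, normal, high
  kind: ordered
  default: normal
domain hormone
  states: low, normal, high
  kind: ordered
  default: normal
domain process
  states: low, normal, high
  kind: ordered
  default: normal
domain presence
  states: absent, present
  kind: categorical
  default: absent
component Cell beta-cell
  threshold: 1
  attributes:
    process, insulin_secretion
    gene, INS
component Cell hepatocyte
  threshold: 1
  attributes:
    gene, PRKAB1
    gene, AGRP
    gene, GLUT4
    gene, PEPCK
    gene, Glucose-6-phosphatase
    process, insulin_resistance
component Cell adipocyte
  threshold: 1
  attributes:
    gene, PPARG
    process, insulin_resistance
component Cell muscle
  threshold: 1
  attributes:
    process, insulin_resistance
    process, glucose_uptake
component Organ circulation
  threshold: 60
  attributes:
    metabolite, glucose
    hormone, insulin
component Drug metformin
  threshold: 1
  attributes:
    presence, status
component Drug pioglitazone
  threshold: 1
  attributes:
    presence, status
component Drug rosiglitazone
  threshold: 1
  attributes:
    presence, status
component Drug troglitazone
  threshold: 1
  attributes:
    presence, status
component Drug saxagliptin
  threshold: 1
  attributes:
    presence, status
component Drug sitagliptin
  threshold: 1
  attributes:
    presence, status
component Drug vildagliptin
  threshold: 1
  attributes:
    presence, status
component Drug miglitol
  threshold: 1
  attributes:
    presence, status
component Drug voglibose
  threshold: 1
  attributes:
    presence, status
component Drug acarbose
  threshold: 1
  attributes:
    presence, status
component Drug exenatide
  threshold: 1
  attributes:
    presence, status
component Drug liraglutide
  threshold: 1
  attributes:
    presence, status
component Drug mitiglinide
  threshold: 1
  attributes:
    presence, status
component Drug nateglinide
  threshold: 1
  attributes:
    presence, status
component Drug repaglinide
  threshold: 1
  attributes:
    presence, status
component Drug chlorpropamide
  threshold: 1
  attributes:
    presence, status
component Drug glipizide
  threshold: 1
  attributes:
    presence, status
component Drug gliquidone
  threshold: 1
  attributes:
    presence, status
component Drug tolbutamide
  threshold: 1
  attributes:
    presence, status
component Drug glimepiride
  threshold: 1
  attributes:
    presence, status
component Drug glyburide
  threshold: 1
  attributes:
    presence, status
component Drug pramlintide
  threshold: 1
  attributes:
    presence, status
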