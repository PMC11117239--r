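[
  {
    "quantity": "ESCRA bearded dragon count",
    "table_value": "21/55 (45.5%)",
    "text_value": 25,
    "resolution": "running text (n = 25) used"
  },
  {
    "quantity": "literature green iguana percent",
    "table_value": "55/219 (28%)",
    "text_value": "55/219 = 25.1%",
    "resolution": "count 55 kept; percent recomputed"
  },
  {
    "quantity": "literature life-stage counts",
    "table_value": "141 unknown + 52 adult + 6 juvenile = 199 of 219",
    "text_value": "arm size 219",
    "resolution": "printed adult/juvenile kept; remainder (161) unknown"
  },
  {
    "quantity": "ESCRA malignancy counts",
    "table_value": "40 malignant + 7 benign + 9 unknown = 56 of 55",
    "text_value": "arm size 55",
    "resolution": "malignant 40, benign 7, undetermined 8"
  },
  {
    "quantity": "literature outcome counts",
    "table_value": "available for 89; categories sum to 62",
    "text_value": "25 + 25 + 11 + 1 known",
    "resolution": "printed category counts kept; remainder unknown"
  },
  {
    "quantity": "distinct neoplasm count",
    "table_value": "85 + 38 - 16 = 107",
    "text_value": "108 neoplasms",
    "resolution": "not a fixture quantity; noted only"
  }
]
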