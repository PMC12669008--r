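{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "nbthreshold comparison report",
  "type": "object",
  "required": ["n", "prevalence", "strategies", "selections",
               "mcnemar_vs_truth", "n_tests"],
  "properties": {
    "n": {"type": "integer", "minimum": 1},
    "prevalence": {"type": "number", "minimum": 0, "maximum": 1},
    "strategies": {
      "type": "array",
      "items": {"enum": ["youden", "nb_intersection"]}
    },
    "selections": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["method", "threshold", "criterion_value",
                     "se", "sp", "acc"],
        "properties": {
          "method": {"type": "string"},
          "threshold": {"type": "number", "minimum": 0, "maximum": 1},
          "criterion_value": {"type": "number"},
          "se": {"type": ["number", "null"]},
          "sp": {"type": ["number", "null"]},
          "acc": {"type": "number"}
        }
      }
    },
    "mcnemar_vs_truth": {
      "type": "object",
      "additionalProperties": {"$ref": "#/$defs/mcnemar"}
    },
    "mcnemar_nb_vs_youden": {"$ref": "#/$defs/mcnemar"},
    "n_tests": {"type": "integer", "minimum": 0}
  },
  "$defs": {
    "mcnemar": {
      "type": "object",
      "required": ["method", "b", "c", "p_value", "p_display"],
      "properties": {
        "method": {"enum": ["exact_binomial", "chi_square_cc"]},
        "b": {"type": "integer", "minimum": 0},
        "c": {"type": "integer", "minimum": 0},
        "statistic": {"type": ["number", "null"]},
        "p_value": {"type": "number", "minimum": 0, "maximum": 1},
        "p_display": {"type": "string"}
      }
    }
  }
}
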