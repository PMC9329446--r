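{
  "type": "object",
  "required": ["parameters", "selected_axes", "totals", "grand_total",
               "explained", "residual", "explained_percent",
               "residual_percent", "fractions", "regions"],
  "properties": {
    "parameters": {
      "type": "object",
      "required": ["alpha", "n_perm", "seed", "design", "keep_policy"],
      "properties": {
        "alpha": {"type": "number"},
        "n_perm": {"type": "integer"},
        "seed": {"type": "integer"},
        "design": {"type": "string"},
        "keep_policy": {"type": "string"},
        "dbmem_threshold": {"type": "string"},
        "variance_divisor": {"type": "string"}
      }
    },
    "selected_axes": {
      "type": "object",
      "additionalProperties": {"type": "array", "items": {"type": "integer"}}
    },
    "totals": {
      "type": "object",
      "additionalProperties": {"type": "number"}
    },
    "grand_total": {"type": "number"},
    "explained": {"type": "number"},
    "residual": {"type": "number"},
    "explained_percent": {"type": "number"},
    "residual_percent": {"type": "number"},
    "fractions": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["residual"],
        "additionalProperties": {"type": "number"}
      }
    },
    "tests": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": "object",
          "required": ["pseudo_F", "p", "n_perm"],
          "properties": {
            "pseudo_F": {"type": "number"},
            "p": {"type": "number"},
            "n_perm": {"type": "integer"}
          }
        }
      }
    },
    "regions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subset", "value", "percent"],
        "properties": {
          "subset": {"type": "string"},
          "value": {"type": "number"},
          "percent": {"type": "number"}
        }
      }
    }
  }
}
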