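{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "veneclipse run report",
  "type": "object",
  "required": ["n_voxels", "n_flipped", "eclipse_present", "coverage"],
  "properties": {
    "n_voxels": {"type": "integer", "minimum": 1},
    "n_flipped": {"type": "integer", "minimum": 0},
    "eclipse_present": {"type": "boolean"},
    "coverage": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["before", "after"],
        "properties": {
          "before": {"$ref": "#/$defs/coverage"},
          "after": {"$ref": "#/$defs/coverage"}
        }
      }
    },
    "smoothness": {
      "type": ["object", "null"],
      "properties": {
        "before": {"type": "number", "minimum": 0},
        "after": {"type": "number", "minimum": 0},
        "percent_smoother": {"type": "number"}
      }
    },
    "inverted_by_area": {"type": ["array", "object"]},
    "congruence": {
      "type": ["object", "null"],
      "properties": {
        "before": {"enum": ["congruent", "incongruent"]},
        "after": {"enum": ["congruent", "incongruent"]}
      }
    }
  },
  "$defs": {
    "coverage": {
      "type": "object",
      "required": ["percent", "complete"],
      "properties": {
        "percent": {
          "type": "array",
          "items": {"type": "number", "minimum": 0, "maximum": 100},
          "minItems": 4, "maxItems": 4
        },
        "complete": {
          "type": "array",
          "items": {"type": "boolean"},
          "minItems": 4, "maxItems": 4
        }
      }
    }
  }
}
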