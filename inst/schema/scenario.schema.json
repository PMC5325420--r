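{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "crosstalksim scenario documents",
  "description": "Shapes of the JSON documents read and written by crosstalksim: screen configurations, module topology fixtures, stimulus profiles and drug regimens. Every document carries schema_version.",
  "definitions": {
    "screen_config": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "schema_version": {"type": "string"},
        "modules": {"type": "array", "items": {"type": "integer", "minimum": 0, "maximum": 8}},
        "anchor_target": {"enum": ["A", "B", "C", "D", "O"]},
        "partner_targets": {"type": "array", "items": {"enum": ["A", "B", "C", "D", "O"]}},
        "dose": {"type": "number", "exclusiveMinimum": 0},
        "partner_dose": {"type": "number", "minimum": 0},
        "stimulus": {"enum": ["S0", "S1", "S2", "S3", "S4", "S5", "S6"]},
        "horizon": {"type": "number", "exclusiveMinimum": 0},
        "h": {"type": "number", "exclusiveMinimum": 0},
        "crosstalk_scale": {"type": "number", "exclusiveMinimum": 0},
        "scale_grid": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}},
        "tol": {"type": "number", "minimum": 0},
        "inhibition": {"enum": ["deactivation", "literal"]}
      }
    },
    "module_topology": {
      "type": "object",
      "required": ["module_id", "V", "K"],
      "properties": {
        "schema_version": {"type": "string"},
        "module_id": {},
        "V": {"type": "array", "items": {"type": "array", "items": {"type": "number"}, "minItems": 5, "maxItems": 5}, "minItems": 5, "maxItems": 5},
        "K": {"type": "array", "items": {"type": "array", "items": {"type": "number"}, "minItems": 5, "maxItems": 5}, "minItems": 5, "maxItems": 5},
        "crosstalk_edges": {"type": "array"},
        "crosstalk_scale": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "stimulus_profile": {
      "type": "object",
      "required": ["name", "segments"],
      "properties": {
        "schema_version": {"type": "string"},
        "name": {"type": "string"},
        "segments": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["t_start", "t_end", "amplitude"],
            "properties": {
              "t_start": {"type": "number", "minimum": 0},
              "t_end": {"type": "number", "exclusiveMinimum": 0},
              "amplitude": {"type": "number", "minimum": 0}
            }
          }
        }
      }
    },
    "drug_regimen": {
      "type": "object",
      "required": ["entries"],
      "properties": {
        "schema_version": {"type": "string"},
        "label": {"type": "string"},
        "entries": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["target", "dose"],
            "properties": {
              "target": {"type": "integer", "minimum": 1, "maximum": 5},
              "dose": {"type": "number", "minimum": 0},
              "t_on": {"type": "number", "minimum": 0}
            }
          }
        }
      }
    }
  }
}
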