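{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Domiscore vulnerability-penalty matrix",
  "type": "object",
  "required": ["grid_version", "rules"],
  "properties": {
    "schema_version": {"type": "integer", "const": 1},
    "grid_version": {"type": "string"},
    "note": {"type": "string"},
    "rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["vulnerability", "variable_id", "trigger_threshold"],
        "properties": {
          "vulnerability": {
            "enum": ["young_children_u4", "elderly_o70", "physical_disability",
                     "visual_disability", "hearing_disability"]
          },
          "variable_id": {"type": "string", "description": "must exist in the referenced grid"},
          "trigger_threshold": {"enum": [1, 2, 3]},
          "penalty_points": {"type": "integer", "const": 1},
          "placeholder": {"type": "boolean", "description": "true when the rule is a stand-in, not a documented one"}
        }
      },
      "description": "each (vulnerability, variable_id) pair appears at most once"
    }
  }
}
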