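{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Domiscore grid definition",
  "type": "object",
  "required": ["schema_version", "version", "categories", "variables"],
  "properties": {
    "schema_version": {"type": "integer", "const": 1},
    "version": {"type": "string", "description": "grid version tag, e.g. 2020-11"},
    "note": {"type": "string"},
    "categories": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "label", "variable_ids"],
        "properties": {
          "id": {"type": "string"},
          "label": {"type": "string"},
          "variable_ids": {
            "type": "array", "minItems": 1,
            "items": {"type": "string"},
            "description": "ordered; must partition the grid's variable set across categories"
          }
        }
      }
    },
    "variables": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "label", "category_id", "position", "sources", "level_descriptions"],
        "properties": {
          "id": {"type": "string", "description": "unique within the grid"},
          "label": {"type": "string"},
          "category_id": {"type": "string"},
          "position": {"type": "integer", "minimum": 1},
          "sources": {
            "type": "array", "minItems": 1,
            "items": {"enum": ["in_situ", "mandatory_diagnostic", "open_data", "occupant_report"]}
          },
          "level_descriptions": {
            "type": "object",
            "required": ["0", "1", "2", "3"],
            "additionalProperties": false,
            "properties": {
              "0": {"type": "string"}, "1": {"type": "string"},
              "2": {"type": "string"}, "3": {"type": "string"}
            }
          },
          "alert_threshold": {"enum": [1, 2, 3], "description": "optional; score at which reporting to authorities is required"},
          "notes": {"type": "string"}
        }
      }
    }
  }
}
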