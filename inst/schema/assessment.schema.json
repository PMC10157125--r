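{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Domiscore dwelling assessment (anonymous by design)",
  "type": "object",
  "required": ["grid_version", "entries"],
  "properties": {
    "grid_version": {"type": "string"},
    "entries": {
      "type": "object",
      "description": "variable id -> score 0-3, or a missing-reason code",
      "additionalProperties": {
        "oneOf": [
          {"type": "integer", "minimum": 0, "maximum": 3},
          {"enum": ["data_unavailable", "site_inaccessible", "diagnosis_unavailable",
                    "description_unclear", "other"]}
        ]
      }
    },
    "dwelling_meta": {
      "type": "object",
      "properties": {
        "housing_type": {"enum": ["collective", "individual"]},
        "setting": {"enum": ["urban", "rural"]},
        "overseas": {"type": "boolean"},
        "tenure": {"enum": ["owner_occupant", "private_rental", "social_housing"]},
        "typology": {"type": "string"}
      },
      "description": "no name, address or other identifying field is accepted anywhere in the document"
    },
    "vulnerabilities": {
      "type": "array",
      "items": {
        "enum": ["young_children_u4", "elderly_o70", "physical_disability",
                 "visual_disability", "hearing_disability"]
      }
    },
    "visit_meta": {
      "type": "object",
      "properties": {
        "minutes_before": {"type": "number"},
        "minutes_during": {"type": "number"},
        "minutes_after": {"type": "number"}
      }
    }
  },
  "not": {
    "anyOf": [
      {"required": ["name"]}, {"required": ["address"]}, {"required": ["email"]},
      {"required": ["phone"]}
    ]
  }
}
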