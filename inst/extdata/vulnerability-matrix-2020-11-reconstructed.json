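{
  "schema_version": 1,
  "grid_version": "2020-11",
  "note": "Two rules follow the published worked examples; rules marked placeholder stand in for the unpublished full penalty table.",
  "rules": [
    {
      "vulnerability": "young_children_u4",
      "variable_id": "ventilation",
      "trigger_threshold": 3,
      "penalty_points": 1,
      "placeholder": false
    },
    {
      "vulnerability": "visual_disability",
      "variable_id": "surface_area",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": false
    },
    {
      "vulnerability": "young_children_u4",
      "variable_id": "lead_paint",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "young_children_u4",
      "variable_id": "window_guards",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "young_children_u4",
      "variable_id": "stairs_safety",
      "trigger_threshold": 2,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "young_children_u4",
      "variable_id": "mold",
      "trigger_threshold": 2,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "elderly_o70",
      "variable_id": "heating",
      "trigger_threshold": 2,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "elderly_o70",
      "variable_id": "fall_protection",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "elderly_o70",
      "variable_id": "stairs_safety",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "elderly_o70",
      "variable_id": "bathroom",
      "trigger_threshold": 2,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "physical_disability",
      "variable_id": "access_circulation",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "physical_disability",
      "variable_id": "surface_area",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "physical_disability",
      "variable_id": "toilet",
      "trigger_threshold": 2,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "visual_disability",
      "variable_id": "natural_light",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "visual_disability",
      "variable_id": "stairs_safety",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "hearing_disability",
      "variable_id": "gas_installation",
      "trigger_threshold": 1,
      "penalty_points": 1,
      "placeholder": true
    },
    {
      "vulnerability": "hearing_disability",
      "variable_id": "neighborhood_safety",
      "trigger_threshold": 2,
      "penalty_points": 1,
      "placeholder": true
    }
  ]
}
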