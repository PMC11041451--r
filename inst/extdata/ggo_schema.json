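{
  "version": "1.0",
  "entity_types": ["pure_ggo_term", "part_solid_ggo_term", "ggo_size", "ggo_quantity", "ggo_location", "ggo_shape_margin", "ggo_solidity", "temporal", "cause_neoplasm", "cause_infectious_inflammatory", "cause_hemorrhage", "cause_other_pulmonary", "status_better", "status_stable", "status_worsen"],
  "relations": {
    "has_size_info": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": "ggo_size"
    },
    "has_number_info": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": "ggo_quantity"
    },
    "has_location_info": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": "ggo_location"
    },
    "has_shape_margin_info": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": "ggo_shape_margin"
    },
    "has_solidity_info": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": "ggo_solidity"
    },
    "has_status": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": ["status_better", "status_stable", "status_worsen"]
    },
    "has_potential_cause": {
      "head_types": ["pure_ggo_term", "part_solid_ggo_term"],
      "tail_types": ["cause_neoplasm", "cause_infectious_inflammatory", "cause_hemorrhage", "cause_other_pulmonary"]
    }
  }
}
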