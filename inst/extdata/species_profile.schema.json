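{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/fertunit/species_profile.schema.json",
  "title": "Species parameter profile",
  "description": "Husbandry metrics for one aquatic species, used to size fertilization units and back-calculate production requirements. Canonical units: volumes in mL, concentrations in sperm cells per mL. The *_ul alternates accept microlitre input and are converted to the mL field on load.",
  "type": "object",
  "properties": {
    "species_name": { "type": "string", "minLength": 1 },
    "eggs_per_female": { "type": "number", "exclusiveMinimum": 0, "description": "Average viable eggs per female" },
    "sperm_egg_ratio": { "type": "number", "exclusiveMinimum": 0, "description": "Sperm cells applied per egg" },
    "sperm_concentration_per_ml": { "type": "number", "exclusiveMinimum": 0, "description": "Sperm cells per mL (fresh post-dilution and/or in-container, per concentration_context)" },
    "container_volume_ml": { "type": "number", "exclusiveMinimum": 0, "description": "Fill volume actually frozen per container, mL (not nominal capacity)" },
    "container_volume_ul": { "type": "number", "exclusiveMinimum": 0, "description": "Microlitre alternate for container_volume_ml" },
    "container_label": { "type": "string", "minLength": 1 },
    "sperm_volume_per_male_ml": { "type": "number", "exclusiveMinimum": 0 },
    "sperm_volume_per_male_ul": { "type": "number", "exclusiveMinimum": 0, "description": "Microlitre alternate for sperm_volume_per_male_ml" },
    "fertilization_rate": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
    "survival_rate": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
    "survival_stage_label": { "type": "string", "minLength": 1 },
    "target_offspring": { "type": "integer", "minimum": 1 },
    "male_pool_minimum": { "type": "integer", "minimum": 0, "default": 0, "description": "SOP floor on males pooled at sperm collection (0 = none)" },
    "concentration_context": { "enum": ["fresh_and_container", "fresh", "container"], "default": "fresh_and_container" }
  },
  "required": [
    "species_name", "eggs_per_female", "sperm_egg_ratio",
    "sperm_concentration_per_ml", "container_label",
    "fertilization_rate", "survival_rate", "survival_stage_label",
    "target_offspring"
  ],
  "oneOf": [
    { "required": ["container_volume_ml"] },
    { "required": ["container_volume_ul"] }
  ],
  "anyOf": [
    { "required": ["sperm_volume_per_male_ml"] },
    { "required": ["sperm_volume_per_male_ul"] }
  ],
  "additionalProperties": false
}
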