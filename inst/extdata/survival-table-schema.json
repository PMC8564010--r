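{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Individual-level survival table (CSV columns)",
  "description": "One row per assayed individual. Comma-separated, UTF-8, header row mandatory, '.' decimal mark. Temperatures in degrees Celsius.",
  "type": "object",
  "properties": {
    "block": {
      "type": "string",
      "description": "Block label (cohort of parents assayed concurrently); categorical."
    },
    "vial": {
      "type": "string",
      "description": "Vial label, unique within block x fert_temp x embryo_temp x assay_temp."
    },
    "fert_temp": {
      "type": "number",
      "description": "Temperature at fertilization (degC); treated as a categorical factor in modelling."
    },
    "embryo_temp": {
      "type": "number",
      "description": "Temperature at embryogenesis (degC); treated as a categorical factor in modelling."
    },
    "assay_temp": {
      "type": "number",
      "description": "Assay temperature at larval development (degC); the continuous axis of the performance curve."
    },
    "outcome": {
      "type": "integer",
      "enum": [0, 1],
      "description": "1 = survived to completion of planktonic development, 0 = died beforehand."
    }
  },
  "required": ["block", "vial", "fert_temp", "embryo_temp", "assay_temp", "outcome"]
}
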