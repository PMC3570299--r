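{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "duoscore study report",
  "type": "object",
  "required": ["flow_ledger", "config"],
  "properties": {
    "flow_ledger": {
      "type": "array",
      "required_columns": ["stage", "n_remaining", "n_excluded", "reason"]
    },
    "regression_table": {
      "type": "array",
      "required_columns": ["outcome", "exposure", "beta", "se", "ci_lo",
                           "ci_hi", "p_value", "n"]
    },
    "qc": {"type": "object"},
    "pca": {"type": "object"},
    "scores": {"type": "object"},
    "instrument_validation": {"$ref": "#/properties/regression_table"},
    "offspring_iq": {"$ref": "#/properties/regression_table"},
    "maternal_iq": {"$ref": "#/properties/regression_table"},
    "diabetes_contrast": {"$ref": "#/properties/regression_table"},
    "confounder_scan": {"type": "object"},
    "config": {"type": "object"}
  }
}
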