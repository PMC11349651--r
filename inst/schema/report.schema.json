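{
  "version": "1.0",
  "description": "Structural schema for capscore pipeline reports: required keys and their primitive types. 'nullable' marks fields that may be null (e.g. ROC when only one class is present).",
  "required": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "schema_version": {"type": "string"},
    "config": {
      "type": "object",
      "required": {
        "input": {"type": "string"},
        "score": {"type": "string"},
        "threshold": {"type": "integer"},
        "npiq_mode": {"type": "string"},
        "decline_method": {"type": "string"},
        "seed": {"type": "integer"}
      }
    },
    "n_subjects": {"type": "integer"},
    "n_scored": {"type": "integer"},
    "excluded": {"type": "array"},
    "subject_scores": {"type": "array"},
    "confusion": {
      "type": "object",
      "required": {
        "tp": {"type": "integer"},
        "fp": {"type": "integer"},
        "tn": {"type": "integer"},
        "fn": {"type": "integer"}
      }
    },
    "metrics": {"type": "object"},
    "roc": {"type": "object", "nullable": true}
  }
}
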