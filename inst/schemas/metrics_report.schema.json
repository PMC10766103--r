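{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bisqus evaluation report",
  "type": "object",
  "required": ["counts", "accuracy", "sensitivity", "specificity", "ppv", "npv"],
  "properties": {
    "counts": {
      "type": "object",
      "required": ["TP", "FP", "TN", "FN"],
      "properties": {
        "TP": {"type": "integer", "minimum": 0},
        "FP": {"type": "integer", "minimum": 0},
        "TN": {"type": "integer", "minimum": 0},
        "FN": {"type": "integer", "minimum": 0}
      }
    },
    "accuracy": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "sensitivity": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "specificity": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "ppv": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "npv": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "auc": {"type": ["number", "null"], "minimum": 0, "maximum": 1}
  }
}
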