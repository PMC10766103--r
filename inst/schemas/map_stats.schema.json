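{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bisqus feature-map comparison report (per frame)",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["frame_id", "mi", "rmse", "avg_mi", "avg_rmse"],
    "properties": {
      "frame_id": {"type": "string"},
      "mi": {"type": "array", "items": {"type": "array", "items": {"type": "number", "minimum": 0}}},
      "rmse": {"type": "array", "items": {"type": "array", "items": {"type": "number", "minimum": 0}}},
      "avg_mi": {"type": "object"},
      "avg_rmse": {"type": "object"}
    }
  }
}
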