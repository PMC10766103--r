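{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bisqus RF container JSON sidecar",
  "type": "object",
  "required": ["dataset", "dtype", "byte_order", "shape", "fs_hz", "f0_hz", "frame_id"],
  "properties": {
    "dataset": {"const": "rf"},
    "dtype": {"const": "float32"},
    "byte_order": {"const": "little"},
    "shape": {"type": "array", "items": {"type": "integer", "minimum": 1}, "minItems": 2, "maxItems": 2},
    "fs_hz": {"type": "number", "exclusiveMinimum": 0},
    "f0_hz": {"type": "number", "exclusiveMinimum": 0},
    "frame_id": {"type": "string"},
    "label": {"enum": ["benign", "malignant"]}
  }
}
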