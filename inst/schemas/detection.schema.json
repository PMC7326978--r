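{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "berryfield detection JSON",
  "description": "Array of per-berry instance records. The mask is either a polygon outline (x right, y down, 0-based pixel coordinates) or an uncompressed column-major run-length encoding with 1-based run starts. Ground-truth records omit the score.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["image", "label"],
    "properties": {
      "image": {"type": "string", "minLength": 1},
      "label": {"enum": ["mature", "immature"]},
      "score": {"type": "number", "minimum": 0, "maximum": 1},
      "polygon": {
        "type": "array",
        "minItems": 3,
        "items": {
          "type": "array",
          "prefixItems": [{"type": "number"}, {"type": "number"}],
          "minItems": 2,
          "maxItems": 2
        }
      },
      "rle": {
        "type": "object",
        "required": ["height", "width", "runs"],
        "properties": {
          "height": {"type": "integer", "minimum": 1},
          "width": {"type": "integer", "minimum": 1},
          "runs": {
            "type": "array",
            "items": {"type": "integer", "minimum": 1},
            "description": "flat [start, length, start, length, ...]"
          }
        }
      }
    },
    "oneOf": [{"required": ["polygon"]}, {"required": ["rle"]}]
  }
}
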