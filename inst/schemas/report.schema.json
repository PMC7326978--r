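{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "berryfield evaluation report JSON",
  "type": "object",
  "required": ["map_table", "errors", "n_images"],
  "properties": {
    "map_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["iou_threshold", "mAP"],
        "properties": {
          "iou_threshold": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
          "AP_mature": {"type": "number", "minimum": 0, "maximum": 1},
          "AP_immature": {"type": "number", "minimum": 0, "maximum": 1},
          "mAP": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "miou": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
    "errors": {
      "type": "object",
      "required": ["one_as_two", "missed", "two_as_one", "partial"],
      "additionalProperties": {"type": "integer", "minimum": 0}
    },
    "n_images": {"type": "integer", "minimum": 0},
    "n_predictions": {"type": "integer", "minimum": 0},
    "n_ground_truth": {"type": "integer", "minimum": 0},
    "primary_threshold": {"type": "number"},
    "pr_curves": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["class", "iou_threshold", "ap", "recall", "precision"],
        "properties": {
          "class": {"enum": ["mature", "immature"]},
          "iou_threshold": {"type": "number"},
          "ap": {"type": "number", "minimum": 0, "maximum": 1},
          "recall": {"type": "array", "items": {"type": "number"}},
          "precision": {"type": "array", "items": {"type": "number"}}
        }
      }
    }
  }
}
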