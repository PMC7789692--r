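{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Triclustering solution (ground truth)",
  "type": "object",
  "required": ["n_triclusters", "dataset_dims", "alphabet_kind", "coverage",
               "missing_pct", "noise_pct", "error_pct", "triclusters"],
  "properties": {
    "n_triclusters": {"type": "integer", "minimum": 0},
    "dataset_dims": {"type": "array", "items": {"type": "integer"},
                     "minItems": 3, "maxItems": 3},
    "alphabet_kind": {"enum": ["real", "integer", "symbolic"]},
    "coverage": {"type": "number", "minimum": 0, "maximum": 1},
    "missing_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "noise_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "error_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "overlap_groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["members", "edges"],
        "properties": {
          "members": {"type": "array", "items": {"type": "integer", "minimum": 0}},
          "edges": {"type": "array",
                    "items": {"type": "array", "items": {"type": "integer"},
                              "minItems": 2, "maxItems": 2}}
        }
      }
    },
    "triclusters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "dims", "n_cells", "rows", "cols", "ctxs",
                     "patterns", "plaid", "missing_pct", "noise_pct",
                     "error_pct"],
        "properties": {
          "id": {"type": "integer", "minimum": 0},
          "dims": {"type": "array", "items": {"type": "integer", "minimum": 1},
                   "minItems": 3, "maxItems": 3},
          "n_cells": {"type": "integer", "minimum": 1},
          "rows": {"type": "array", "items": {"type": "integer", "minimum": 0}},
          "cols": {"type": "array", "items": {"type": "integer", "minimum": 0}},
          "ctxs": {"type": "array", "items": {"type": "integer", "minimum": 0}},
          "patterns": {"type": "array",
                       "items": {"enum": ["OrderPreserving", "Constant",
                                          "Additive", "Multiplicative", "None"]},
                       "minItems": 3, "maxItems": 3},
          "profile": {"enum": ["increasing", "decreasing", "random"]},
          "plaid": {"enum": ["additive", "multiplicative", "interpoled",
                             "none", "no_overlap"]},
          "missing_pct": {"type": "number", "minimum": 0, "maximum": 100},
          "noise_pct": {"type": "number", "minimum": 0, "maximum": 100},
          "error_pct": {"type": "number", "minimum": 0, "maximum": 100}
        }
      }
    }
  }
}
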