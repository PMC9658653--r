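{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bssd scenario report",
  "type": "object",
  "required": ["schema_version", "design", "frequentist_n", "priors", "cells"],
  "properties": {
    "schema_version": {"type": "string"},
    "panel": {
      "type": ["object", "null"],
      "properties": {
        "opinions": {"type": "array", "items": {"type": "number"}},
        "mean": {"type": "number"},
        "variance": {"type": "number"},
        "n_experts": {"type": "integer"}
      }
    },
    "design": {
      "type": "object",
      "required": ["l", "coverage"],
      "properties": {
        "l": {"type": "number"},
        "coverage": {"type": "number"},
        "placement": {"type": "string"},
        "woc_space": {"type": "string"},
        "round_prior": {"type": "boolean"},
        "degree": {"type": "number"},
        "seed": {"type": "integer"}
      }
    },
    "frequentist_n": {"type": "integer"},
    "bounds": {"type": "array", "items": {"type": "integer"}},
    "priors": {"type": "object"},
    "cells": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["scenario", "criterion", "n_opt", "value", "failed"],
        "properties": {
          "scenario": {"type": "string"},
          "criterion": {"type": "string"},
          "n_opt": {"type": ["integer", "null"]},
          "value": {"type": ["number", "null"]},
          "failed": {"type": "boolean"}
        }
      }
    }
  }
}
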