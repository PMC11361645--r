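{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "gtpasekin run configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "seeds": {
      "type": "array", "items": {"type": "integer", "minimum": 0},
      "minItems": 1,
      "description": "Seeds for replicated simulations."
    },
    "ladder_uM": {
      "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
      "minItems": 3,
      "description": "Protein concentrations of the stopped-flow ladder, uM."
    },
    "reporter_conc_uM": {"type": "number", "exclusiveMinimum": 0},
    "noise_sd_frac": {
      "type": "number", "minimum": 0,
      "description": "Trace noise sd as a fraction of amplitude."
    },
    "hydrolysis_noise_sd": {
      "type": "number", "minimum": 0,
      "description": "Absolute noise sd on GTP fractions."
    },
    "pools": {
      "type": "object",
      "properties": {
        "gtp_uM": {"type": "number", "minimum": 0},
        "gdp_uM": {"type": "number", "minimum": 0}
      }
    },
    "thresholds": {
      "type": "object",
      "properties": {
        "r1": {"type": "number", "exclusiveMinimum": 0},
        "f_gtp": {"type": "number", "minimum": 0, "maximum": 1},
        "rel_threshold": {"type": "number"},
        "min_area": {"type": "integer", "minimum": 1},
        "max_dist": {"type": "number", "minimum": 0}
      }
    },
    "out_dir": {"type": "string"}
  }
}
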