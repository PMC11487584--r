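{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "diffuseQC curve sidecar",
  "type": "object",
  "required": ["kind"],
  "properties": {
    "kind": {"enum": ["dtof", "irf", "g2"]},
    "wavelength": {"type": "number", "exclusiveMinimum": 0},
    "n_averaged": {"type": "number", "minimum": 1},
    "background_level": {"type": "number", "minimum": 0},
    "fwhm": {"type": "number", "exclusiveMinimum": 0},
    "count_rate": {"type": "number", "minimum": 0},
    "n_channels": {"type": "number", "minimum": 1},
    "duration": {"type": "number", "exclusiveMinimum": 0},
    "rho": {"type": "number", "exclusiveMinimum": 0},
    "beta": {"type": "number"},
    "seed": {"type": "integer"}
  },
  "allOf": [
    {"if": {"properties": {"kind": {"const": "dtof"}}},
     "then": {"required": ["wavelength", "n_averaged", "background_level"]}},
    {"if": {"properties": {"kind": {"const": "irf"}}},
     "then": {"required": ["fwhm"]}},
    {"if": {"properties": {"kind": {"const": "g2"}}},
     "then": {"required": ["count_rate", "n_channels", "duration"]}}
  ]
}
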