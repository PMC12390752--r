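{
  "comment": "Two-user hierarchy: admin plus one user key per carrier against both carriers; cells are CorrInfo fractions.",
  "type": "hierarchy",
  "designs": [
    {"design_id": "DDC-1"},
    {"design_id": "DDC-2"}
  ],
  "texts": ["PEACE", "LOVE"],
  "scheme": "a5",
  "n_structures": 1000,
  "seed": 40401,
  "params": {}
}
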