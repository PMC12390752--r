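{
  "comment": "Marker-only transformation experiment: untriggered vs admin vs matched user key on an empty data array (the two conformation markers carry the signal).",
  "type": "conditions",
  "text": "",
  "scheme": "a5",
  "keys": ["none", "admin", "user"],
  "n_structures": 1000,
  "seed": 20201,
  "params": {}
}
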