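{
  "comment": "Three-word message accessed with no key, the admin key, and the matched user key; one YieldTable row per word and condition.",
  "type": "conditions",
  "text": "DNA NANO TECH",
  "scheme": "a5",
  "keys": ["none", "admin", "user"],
  "n_structures": 1000,
  "seed": 30301,
  "params": {}
}
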