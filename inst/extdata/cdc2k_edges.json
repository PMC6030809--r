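{
  "columns": ["ID(reaction)", "TYPE(edge)", "ID(species)"],
  "data": [
    ["100233", "HAS_PRODUCT", "100186"],
    ["100229", "HAS_REACTANT", "100186"]
  ]
}
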