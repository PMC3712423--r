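{
  "B": ["16", "11"],
  "E": ["6", "11"],
  "F": ["9", "15"],
  "G": ["9", "15", "18"],
  "H": ["9", "15", "19"]
}
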