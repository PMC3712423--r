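{
  "A": ["10", "13"],
  "B": ["17", "13"],
  "C": ["2", "10", "13"],
  "D": ["1", "2"]
}
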