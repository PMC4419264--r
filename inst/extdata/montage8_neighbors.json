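{
  "C3":  ["Cz", "CP1", "P3"],
  "Cz":  ["C3", "C4", "CP1", "CP2"],
  "C4":  ["Cz", "CP2", "P4"],
  "CP1": ["C3", "Cz", "CP2", "P3", "Pz"],
  "CP2": ["Cz", "C4", "CP1", "Pz", "P4"],
  "P3":  ["C3", "CP1", "Pz"],
  "Pz":  ["CP1", "CP2", "P3", "P4"],
  "P4":  ["C4", "CP2", "Pz"]
}
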