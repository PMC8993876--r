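{
  "JAK2": "JAK2/3",
  "JAK3": "JAK2/3",
  "IDH1": "IDH1/2",
  "IDH2": "IDH1/2"
}
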