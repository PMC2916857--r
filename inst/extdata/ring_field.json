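{
  "kind": "ring_disc",
  "hullRadius": 150,
  "ringRadius": 90,
  "ringWidth": 25
}
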