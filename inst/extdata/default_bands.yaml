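- label: frustule
  ri_min: 1.352
  ri_max: 1.357
  color: black
- label: protoplasm
  ri_min: 1.363
  ri_max: 1.381
  color: green
- label: vacuole
  ri_min: 1.388
  ri_max: 1.395
  color: blue
- label: chloroplast
  ri_min: 1.403
  ri_max: 1.436
  color: red
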