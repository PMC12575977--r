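{
  "fx": 1400, "fy": 1400, "cx": 960, "cy": 600,
  "baseline_mm": 42, "width": 1920, "height": 1200
}
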