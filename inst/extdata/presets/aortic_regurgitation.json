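{
  "name": "aortic_regurgitation",
  "description": "Aortic regurgitation: closed aortic valve area 0.0 -> 0.2 cm2.",
  "duration": 60,
  "patches": [{"path": "valves.aortic.a_min", "value": 0.2}],
  "events": []
}
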