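{
  "name": "aortic_stenosis",
  "description": "Aortic stenosis: open aortic valve area 5.0 -> 0.7 cm2.",
  "duration": 60,
  "patches": [{"path": "valves.aortic.a_max", "value": 0.7}],
  "events": []
}
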