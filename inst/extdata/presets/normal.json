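{
  "name": "normal",
  "description": "Baseline healthy resting adult; identity patch.",
  "duration": 60,
  "patches": [],
  "events": []
}
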