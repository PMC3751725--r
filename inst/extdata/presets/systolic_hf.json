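{
  "name": "systolic_hf",
  "description": "Systolic left heart failure: LV maximum elastance 2.8 -> 1.0 mmHg/ml.",
  "duration": 60,
  "patches": [{"path": "chambers.lv.e_max", "value": 1.0}],
  "events": []
}
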