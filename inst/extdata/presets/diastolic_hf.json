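{
  "name": "diastolic_hf",
  "description": "Diastolic left heart failure: LV basal passive elastance 0.05 -> 0.12 mmHg/ml.",
  "duration": 60,
  "patches": [{"path": "chambers.lv.e_min", "value": 0.12}],
  "events": []
}
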