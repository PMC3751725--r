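{
  "name": "arteriosclerosis",
  "description": "Progressive arteriosclerosis: incremental Young's modulus raised to 6000 mmHg in every vascular segment (vary 2000-6000 for the progression).",
  "duration": 60,
  "patches": [{"path": "global.young_modulus", "value": 6000}],
  "events": []
}
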