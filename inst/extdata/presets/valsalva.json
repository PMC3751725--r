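{
  "name": "valsalva",
  "description": "Valsalva maneuver: intrathoracic pressure 0 -> +10 mmHg for 20 s (t = 20..40 s). Enable the baroreflex separately to compare reflex on/off.",
  "duration": 60,
  "patches": [],
  "events": [
    {"t_start": 20, "t_end": 40, "path": "global.intrathoracic_pressure", "value": 10}
  ]
}
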