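{
  "name": "exercise",
  "description": "Stepwise moderate exercise: HR +100%, LV/RV contractility +50%, systemic then pulmonary resistance-artery diameters +50%; 25 s per stage.",
  "duration": 160,
  "patches": [],
  "events": [
    {
      "t_start": 30,
      "t_end": 160,
      "path": "global.heart_rate",
      "value": 144
    },
    {
      "t_start": 60,
      "t_end": 160,
      "path": "chambers.lv.e_max",
      "value": 4.2
    },
    {
      "t_start": 60,
      "t_end": 160,
      "path": "chambers.rv.e_max",
      "value": 0.72
    },
    {
      "t_start": 90,
      "t_end": 160,
      "path": "segments.sys_arteriolae.radius0",
      "value": 0.0075
    },
    {
      "t_start": 90,
      "t_end": 160,
      "path": "segments.r_car_arteriolae.radius0",
      "value": 0.006
    },
    {
      "t_start": 90,
      "t_end": 160,
      "path": "segments.l_car_arteriolae.radius0",
      "value": 0.006
    },
    {
      "t_start": 120,
      "t_end": 160,
      "path": "segments.pu_arteriolae.radius0",
      "value": 0.009
    }
  ]
}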