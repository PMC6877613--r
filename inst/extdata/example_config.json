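{
  "box_side": 96,
  "phi": 0.1,
  "h": 30,
  "L": 2,
  "dt": 0.01,
  "t_total": 30,
  "save_interval": 0.25,
  "hydro_interval": 0.05,
  "hydrodynamics_on": true,
  "seed": 1
}
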