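{
  "cells": [
    {"phi": 0.01, "L": 2, "h": 30, "hydro": true},
    {"phi": 0.05, "L": 2, "h": 30, "hydro": true},
    {"phi": 0.1,  "L": 2, "h": 30, "hydro": true},
    {"phi": 0.2,  "L": 2, "h": 30, "hydro": true}
  ],
  "seeds": [1, 2, 3],
  "t_burn": 15,
  "base_config": {
    "box_side": 96,
    "dt": 0.01,
    "t_total": 30,
    "save_interval": 0.25,
    "hydro_interval": 0.05
  }
}
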