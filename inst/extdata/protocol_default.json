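{
  "max_gradient_mT_m": 80,
  "waveform_dt_ms": 0.01,
  "sequences": [
    {
      "kind": "OGSE",
      "name": "OGSE_25Hz",
      "delta_ms": 41.52,
      "Delta_ms": 60,
      "freq_hz": 25,
      "n_cycles": 1,
      "b_s_mm2": [0, 250, 500, 750, 1000],
      "ramp_ms": 1
    },
    {
      "kind": "OGSE",
      "name": "OGSE_50Hz",
      "delta_ms": 41.52,
      "Delta_ms": 50,
      "freq_hz": 50,
      "n_cycles": 2,
      "b_s_mm2": [0, 250, 500],
      "ramp_ms": 1
    },
    {
      "kind": "PGSE",
      "name": "PGSE",
      "delta_ms": 13.52,
      "Delta_ms": 74,
      "freq_hz": {},
      "n_cycles": {},
      "b_s_mm2": [0, 250, 500, 750, 1000],
      "ramp_ms": 1
    }
  ]
}
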