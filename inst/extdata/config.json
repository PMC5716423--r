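{
  "tolerances": {
    "mlc_mm": 3,
    "gantry_deg": 2,
    "jaw_mm": 3,
    "sweep": [1, 2, 3, 5]
  },
  "bin_width_mm": 0.5,
  "bin_width_deg": 0.5,
  "alerts": [
    {
      "metric": "P3mm_mlc",
      "comparator": "below",
      "threshold": 85,
      "scope": "fraction"
    },
    {
      "metric": "P3mm_mlc",
      "comparator": "below",
      "threshold": 90,
      "scope": "window",
      "window": 5
    },
    {
      "metric": "P2deg_gantry",
      "comparator": "below",
      "threshold": 90,
      "scope": "fraction"
    }
  ]
}
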