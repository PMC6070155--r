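{
  "output_dir": "sticcs_demo_output",
  "seed": 1,
  "conditions": [
    {
      "name": "guided_fast",
      "n_cells": 3,
      "sim": { "explorative_fraction": 0.3, "growth_speed_mean": 20 }
    },
    {
      "name": "explorative_slow",
      "n_cells": 3,
      "sim": { "explorative_fraction": 0.6, "growth_speed_mean": 12 }
    }
  ],
  "sim": { "image_shape": [64, 64], "n_frames": 100 },
  "preprocess": {},
  "sticcs": {},
  "tracking": {},
  "stats": {
    "reference": "guided_fast",
    "metrics": ["assembly_speed_um_min", "cross_fraction_pct",
                "track_assembly_rate_um_min"]
  },
  "write_figures": true
}
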