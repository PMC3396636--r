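{
  "half_life": 20.7529095976032,
  "k_true": 0.0334,
  "j": 0.0004,
  "unit": "min",
  "steady_state_quantity": 1,
  "plateau_fraction": 0,
  "design": {
    "kind": "reverse_chase",
    "timepoints": [0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100],
    "unit": "min",
    "replicates": 1,
    "tech_reps": 3
  },
  "noise": {
    "ct_sd": 0,
    "count_cv": 0,
    "seeding_cv": 0,
    "seed": 102
  },
  "seed_cells": 10000
}
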