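{
  "half_life": "Inf",
  "k_true": 0,
  "j": 0.115524530093324,
  "unit": "h",
  "steady_state_quantity": 1,
  "plateau_fraction": 0,
  "design": {
    "kind": "conventional",
    "timepoints": [0, 6, 12, 18, 24],
    "unit": "h",
    "replicates": 1,
    "tech_reps": 3
  },
  "noise": {
    "ct_sd": 0,
    "count_cv": 0,
    "seeding_cv": 0,
    "seed": 101
  },
  "seed_cells": 10000
}
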