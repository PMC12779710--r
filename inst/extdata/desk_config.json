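{
  "variant": "default",
  "seed": 1,
  "network": {
    "n_e": 48,
    "n_i": 12,
    "n_channels": 16,
    "p_ee": 0.16,
    "p_ei": 0.205,
    "p_ie": 0.252,
    "p_ii": 0.284,
    "lognormal_mu": -0.64,
    "lognormal_sigma": 0.51,
    "i_scale": 10,
    "input_w_min": 0,
    "input_w_max": 0.4,
    "input_frac": 0.5,
    "dale_enforced": true,
    "remove_ee": false,
    "output_encoding": "single",
    "seed": 1
  },
  "task": {
    "T_len": 1020,
    "block_len": 68,
    "n_blocks": 15,
    "change_window": [125, 875],
    "n_unique": 100,
    "label_high": 1
  },
  "train": {
    "batch_size": 10,
    "n_updates": 3000,
    "lr": 0.005,
    "lambda_rate": 1250,
    "rate_target": 0.02,
    "snapshot_every": 100,
    "mode": "dual"
  },
  "analyze": {
    "n_eval": 40
  }
}
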