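{
  "version": 1,
  "comment": "Three-level impairment presets for the synthetic study generator. Values are in normalized skeleton units (total bone length 1) and frames. Jitter ranges are multiplicative (amplitude_jitter, tempo_jitter) or uniform-integer (start_delay_range); anthropometric_scale_range is sampled once per participant.",
  "anthropometric_scale_range": [0.85, 1.2],
  "levels": {
    "good": {
      "amplitude_factor": 1.0,
      "tempo_factor": 1.0,
      "start_delay": 1,
      "pose_noise_sd": 0.0,
      "amplitude_jitter": [0.96, 1.0],
      "tempo_jitter": [0.98, 1.02],
      "start_delay_range": [0, 2]
    },
    "intermediate": {
      "amplitude_factor": 0.7,
      "tempo_factor": 0.9,
      "start_delay": 2,
      "pose_noise_sd": 0.0005,
      "amplitude_jitter": [0.93, 1.07],
      "tempo_jitter": [0.97, 1.03],
      "start_delay_range": [1, 4]
    },
    "bad": {
      "amplitude_factor": 0.4,
      "tempo_factor": 0.8,
      "pose_noise_sd": 0.0015,
      "start_delay": 4,
      "amplitude_jitter": [0.9, 1.1],
      "tempo_jitter": [0.97, 1.03],
      "start_delay_range": [2, 6]
    }
  }
}
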