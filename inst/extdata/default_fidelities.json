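{
  "comment": "Per-feature observer fidelities for the three default reading rounds. Calibrated once so the pooled pairwise kappas follow the 0.77 / 0.66 / 0.56 agreement trajectory while the diagnostically dominant features (margin, echo pattern) stay at a constant fidelity across rounds; the four minor descriptors absorb the agreement decline.",
  "observations": [
    {
      "observation_id": "obs1",
      "interval_label": "baseline",
      "fidelity": {
        "shape": 0.649, "orientation": 0.649, "margin": 0.96,
        "lesion_boundary": 0.649, "echo_pattern": 0.96,
        "posterior_features": 0.649
      }
    },
    {
      "observation_id": "obs2",
      "interval_label": "+1 month",
      "fidelity": {
        "shape": 1.0, "orientation": 1.0, "margin": 0.96,
        "lesion_boundary": 1.0, "echo_pattern": 0.96,
        "posterior_features": 1.0
      }
    },
    {
      "observation_id": "obs3",
      "interval_label": "+3 months",
      "fidelity": {
        "shape": 0.464, "orientation": 0.464, "margin": 0.96,
        "lesion_boundary": 0.464, "echo_pattern": 0.96,
        "posterior_features": 0.464
      }
    }
  ]
}
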