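{
  "n_patients": 126,
  "seed": 20180201,
  "planted_graph": {
    "names": ["age", "days_to_ragt", "gaa_baseline", "sias_hip_flexion", "sias_knee_extension", "sias_ankle_dorsiflexion", "sias_touch", "sias_position_sense", "sias_trunk_verticality", "sias_abdominal", "fim_comprehension", "fim_expression", "fim_social_interaction", "fim_problem_solving", "fim_memory"],
    "B": [
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0.3, 0, 0, 0, 0, 0.4, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0.5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0.45, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0.45, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.45, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.4, 0]
    ],
    "noise": ["uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform", "uniform"],
    "scales": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1],
    "order": [1, 2, 4, 5, 6, 7, 8, 9, 3, 10, 11, 12, 13, 14, 15]
  },
  "outcome_coefs": [2.05284085988266, 1.21491274436427, -1.66073120682165, 0.470003629245736, 0.405465108108164, 0.470003629245736, 0.405465108108164, 0.405465108108164, 0.587786664902119],
  "intercept": {},
  "target_prevalence": 0.523809523809524,
  "marginals": {
    "age": {
      "kind": "continuous"
    },
    "days_to_ragt": {
      "kind": "continuous"
    },
    "gaa_baseline": {
      "kind": "ordinal",
      "values": [1, 2, 3, 4],
      "probs": [0.15, 0.3, 0.4, 0.15]
    },
    "sias_hip_flexion": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3, 4, 5],
      "probs": [0.5, 0.25, 0.13, 0.07, 0.03, 0.02]
    },
    "sias_knee_extension": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3, 4, 5],
      "probs": [0.55, 0.25, 0.1, 0.05, 0.03, 0.02]
    },
    "sias_ankle_dorsiflexion": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3, 4, 5],
      "probs": [0.8, 0.1, 0.05, 0.03, 0.01, 0.01]
    },
    "sias_touch": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3],
      "probs": [0.3, 0.25, 0.3, 0.15]
    },
    "sias_position_sense": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3],
      "probs": [0.35, 0.25, 0.25, 0.15]
    },
    "sias_trunk_verticality": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3],
      "probs": [0.08, 0.12, 0.28, 0.52]
    },
    "sias_abdominal": {
      "kind": "ordinal",
      "values": [0, 1, 2, 3],
      "probs": [0.3, 0.28, 0.27, 0.15]
    },
    "fim_comprehension": {
      "kind": "ordinal",
      "values": [1, 2, 3, 4, 5, 6, 7],
      "probs": [0.06, 0.1, 0.18, 0.26, 0.2, 0.12, 0.08]
    },
    "fim_expression": {
      "kind": "ordinal",
      "values": [1, 2, 3, 4, 5, 6, 7],
      "probs": [0.08, 0.18, 0.14, 0.22, 0.2, 0.1, 0.08]
    },
    "fim_social_interaction": {
      "kind": "ordinal",
      "values": [1, 2, 3, 4, 5, 6, 7],
      "probs": [0.05, 0.09, 0.16, 0.2, 0.25, 0.15, 0.1]
    },
    "fim_problem_solving": {
      "kind": "ordinal",
      "values": [1, 2, 3, 4, 5, 6, 7],
      "probs": [0.1, 0.2, 0.25, 0.2, 0.13, 0.07, 0.05]
    },
    "fim_memory": {
      "kind": "ordinal",
      "values": [1, 2, 3, 4, 5, 6, 7],
      "probs": [0.1, 0.18, 0.27, 0.15, 0.16, 0.08, 0.06]
    }
  }
}
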