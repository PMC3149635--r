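label: fig4d
description: >
  As fig4c but after strong training (S = 0.95 in the shock-learning
  session): t = 10 no longer extinguishes in controls, while anisomycin
  now produces reconsolidation blockade.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2, S: 0.95}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10}
      - {kind: TEST, label: post-reexposure}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2, S: 0.95}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10, S: 0}
      - {kind: TEST, label: post-reexposure}
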