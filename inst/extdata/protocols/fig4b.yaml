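label: fig4b
description: >
  As fig4a, but the shock memory is strengthened by S = 0.95 during its
  learning session: strong training protects against reconsolidation
  blockade.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2, S: 0.95}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 4}
      - {kind: TEST, label: post-reexposure}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2, S: 0.95}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 4, S: 0}
      - {kind: TEST, label: post-reexposure}
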