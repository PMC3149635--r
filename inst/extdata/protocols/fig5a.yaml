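label: fig5a
description: >
  Memory-enhancing drug (S = 0.95) during reexposure: slight freezing
  increase in reconsolidation conditions (t = 4), improved extinction
  and lower freezing in extinction conditions (t = 8).
arms:
  vehicle_t4:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 4}
      - {kind: TEST, label: post-reexposure}
  enhancer_t4:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 4, S: 0.95}
      - {kind: TEST, label: post-reexposure}
  vehicle_t8:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 8}
      - {kind: TEST, label: post-reexposure}
  enhancer_t8:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 8, S: 0.95}
      - {kind: TEST, label: post-reexposure}
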