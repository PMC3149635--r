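label: s7_enhanced_D
description: >
  Enhanced mismatch-induced degradation (D = 1.5) during a t = 7.5
  reexposure lowers freezing relative to vehicle by impairing
  reinforcement of the shock memory.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 7.5}
      - {kind: TEST, label: post-reexposure}
  enhanced_D:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 7.5, D: 1.5}
      - {kind: TEST, label: post-reexposure}
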