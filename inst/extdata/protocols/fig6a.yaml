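label: fig6a
description: >
  Degradation blockade and reconsolidation (t = 6): D = 0 alone has no
  effect, but reverses the amnestic effect of anisomycin when the two
  are combined.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: post-reexposure}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 6, S: 0}
      - {kind: TEST, label: post-reexposure}
  deg_block:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: post-reexposure}
  aniso_deg_block:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 6, S: 0, D: 0}
      - {kind: TEST, label: post-reexposure}
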