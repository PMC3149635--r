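label: fig4a
description: >
  Anisomycin in an intermediate reexposure (t = 4) after regular
  training (S = 0.8): reconsolidation blockade lowers freezing.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 4}
      - {kind: TEST, label: post-reexposure}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 4, S: 0}
      - {kind: TEST, label: post-reexposure}
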