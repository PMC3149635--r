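label: fig3d
description: >
  Anisomycin in a reexposure session of duration t = 10.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10}
      - {kind: TEST, label: post-reexposure}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10, S: 0}
      - {kind: TEST, label: post-reexposure}
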