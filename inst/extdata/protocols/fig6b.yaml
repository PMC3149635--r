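label: fig6b
description: >
  Degradation blockade and multiple-session extinction: D = 0 during
  six t = 6 reexposures blocks the decline in freezing.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: extinction-1}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: extinction-2}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: extinction-3}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: extinction-4}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: extinction-5}
      - {kind: REEXPOSE, t: 6}
      - {kind: TEST, label: extinction-6}
  deg_block:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: extinction-1}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: extinction-2}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: extinction-3}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: extinction-4}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: extinction-5}
      - {kind: REEXPOSE, t: 6, D: 0}
      - {kind: TEST, label: extinction-6}
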