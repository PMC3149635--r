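label: fig2c
description: >
  Fear conditioning and single-session extinction: freezing is low after
  learning the unrelated memory, rises after shock learning, and falls
  again after one long reexposure (t = 10).
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TEST, label: post-memory-1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-memory-2}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10}
      - {kind: TEST, label: post-extinction}
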