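label: fig2d
description: >
  Multiple-session extinction: six reexposures of intermediate duration
  (t = 6), with a retrieval test after each.  Time-related decay occurs
  only before the first extinction session.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TEST, label: post-memory-1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-memory-2}
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
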