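label: fig3a
description: >
  Anisomycin at initial learning (S = 0 in the shock-learning session)
  blocks fear acquisition; freezing stays at baseline.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TEST, label: pre-learning}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-learning}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TEST, label: pre-learning}
      - {kind: TRAIN, pattern: 2, S: 0}
      - {kind: TEST, label: post-learning}
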