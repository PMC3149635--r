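label: fig3e
description: >
  Anisomycin without contextual reexposure: the reexposure session is
  replaced by learning of a novel, unrelated pattern, which leaves the
  shock-memory synapses untouched, so the drug has no effect and
  freezing stays comparable in both arms.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: TRAIN_UNRELATED, label: unrelated-session}
      - {kind: TEST, label: post-session}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: TEST, label: post-training}
      - {kind: DECAY}
      - {kind: TRAIN_UNRELATED, S: 0, label: unrelated-session}
      - {kind: TEST, label: post-session}
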