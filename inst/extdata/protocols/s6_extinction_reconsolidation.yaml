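label: s6_extinction_reconsolidation
description: >
  Reconsolidation of the extinction memory: after extinction (t = 10),
  a t = 5 reexposure retrieves the now-dominant extinction memory;
  anisomycin in that session raises freezing again by blocking its
  reconsolidation.
arms:
  vehicle:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10}
      - {kind: TEST, label: post-extinction}
      - {kind: REEXPOSE, t: 5}
      - {kind: TEST, label: post-reexposure}
  anisomycin:
    sessions:
      - {kind: TRAIN, pattern: 1}
      - {kind: TRAIN, pattern: 2}
      - {kind: DECAY}
      - {kind: REEXPOSE, t: 10}
      - {kind: TEST, label: post-extinction}
      - {kind: REEXPOSE, t: 5, S: 0}
      - {kind: TEST, label: post-reexposure}
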