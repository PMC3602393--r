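# End-to-end smoke experiment: a small control network, all three drives,
# plus a single lesion point scored against baseline. Runs in well under a
# minute on one CPU.
experiment: smoke
master_seed: 1
params:
  populations: {pyramidal: 24, basket: 6, chandelier: 6, calretinin: 4}
drive:
  duration_ms: 600
  transient_ms: 100
lesion:
  nmda_reduction: 0.30
  spine_reduction: 0.30
  gaba_pair: 0
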