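# Run configuration for the analysis drivers (01_simulate ... 06_report).
# `profile: full` runs the full 456-neuron / 10,000-permutation scale;
# `ci` keeps 1,000 permutations and reduced time-course resolution.  The
# neuron counts below are a moderate ensemble (176 cells) that exhibits
# every population effect while keeping a full run around a minute.
profile: ci
session:
  seed: 1
  n_trials: 128
  error_rate: 0.15
  counts:
    untuned: 60
    item_unitized: 40
    item_nonunitized: 10
    background: 16
    convergent: 16
    transferring: 12
    targeting: 16
    multiphase: 6
analysis:
  n_perm: 1000
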