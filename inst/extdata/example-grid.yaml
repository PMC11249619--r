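# Example run configuration: 2 reliabilities x 2 observed correlations,
# single-item symmetric outcome, 2000 sibling pairs, 500 replicates.
grid:
  n_pairs: [2000]
  n_reps: [500]
  rho_obs: [0.2, 0.4]
  reliability: [1.0, 0.7]
  beta: [0.3]
  outcome_kind: [single_item]
  symmetry: [symmetric]
seed: 20240616
alpha: [0.05, 0.01, 0.001]
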