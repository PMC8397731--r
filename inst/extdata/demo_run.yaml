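# Demo pipeline configuration: simulate a small planted collection and run
# every stage. Usage:
#   sedipan run --config demo_run.yaml --out demo_out --seed 11
# (out_dir below is used when --out is not given)
seed: 11
out_dir: demo_out
simulate:
  n_core: 5
  n_order_specific: {NC: 1, NS: 1, NT: 1, NP: 2}
  n_subclade_specific: {theta: 1, iota: 1}
  n_sediment_specific: 2
  n_deep_shared: 1
  n_singletons: 4
  dropout_prob: 0
cluster:
  min_identity: 0.35
  min_cov_long: 0.7
  min_cov_short: 0.7
partition:
  sediment_clades: [theta, delta, iota]
  deep_clades: [alpha, gamma]
ani:
  enabled: true
  length_bp: 20000
  rates: [0.02, 0.05]
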