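# Two-site synthetic federation: balanced site A, class-imbalanced site B
# with a scanner-style intensity shift. Run with:
#   Rscript inst/cli/fedglio.R train --config example_experiment.yaml
sites:
  - site_id: siteA
    n_class0: 10
    n_class1: 10
    seed: 11
  - site_id: siteB
    n_class0: 12
    n_class1: 4
    domain_shift: {gain: 0.95, offset: 0.0, gamma: 0.35}
    seed: 12
preprocess:
  n_per_view: 5
  size: 16
model_preset: tiny
fl:
  rounds: 10
  K: 5
  batch_size: 30
  eta: 0.01
  alpha: 0.01
  weight_decay: 0.0001
  momentum: 0.9
  h_scale: 0.01
  algorithm: etfeddyn
mapping: false
n_runs: 2
master_seed: 1
out_dir: results_example
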