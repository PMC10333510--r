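# Minimal end-to-end smoke configuration: a tiny two-class cohort with
# short recordings and a heavily truncated training run. Intended for
# quick pipeline verification, not for meaningful accuracy.
seed: 7
out_dir: smoke_out
simulate:
  n_per_class:
    NC: 3
    SZ: 3
  duration: 6
  fs: 1000
train:
  batch_size: 128
  max_epochs: 4
  patience: 3
embed:
  method: pca
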