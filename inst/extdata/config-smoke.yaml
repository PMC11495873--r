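# Tiny end-to-end smoke configuration: a two-transcript synthetic corpus,
# small model, two training epochs. Finishes in well under a minute.
outdir: nanodrach_smoke
seed: 7
simulate:
  n_refs: 2
  ref_length: 120
  drach_density: 0.02
  reads_per_site: 24
  noise_scale: 1.0
  trace_sharpness: 0.9
  trace_perturb: 0.2
  m6a_offset: 5.0
featurize:
  min_coverage: 20
  max_reads: 1000
model:
  channels: 6
  skip_channels: 8
  post_channels: 8
  embed_dim: 1024
  q_dim: 16
  v_dim: 16
  stoich_hidden: 16
train:
  epochs: 4
  pretrain_epochs: 2
  lr: 0.001
  stoich_epochs: 5
predict:
  threshold: 0.5
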