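# Desk-scale smoke configuration: 12 patients, 10-minute recordings, a small
# encoder. Exercises the full chain end to end in a few minutes on one CPU.
seed: 7
sim:
  n_patients: 12
  paf_fraction: 0.5
  duration_s: 600
  sve_rate_paf: 80
  p_wave_effect: 0.3
preprocess:
  setting: 1
encoder:
  channels: [8, 16, 32]
  latent_dim: 16
  batch_size: 128
  max_epochs: 4
  patience: 2
patient:
  n_trees: 100
  n_bins: 6
eval:
  k: 3
  n_boot: 200
  train_segments_per_patient: 25
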