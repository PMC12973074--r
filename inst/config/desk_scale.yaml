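# Desk-scale experiment profile: 16-channel synthetic session, reduced
# model, 50 Hz analysis rate. Values mirror desk_scale_experiment_config().
global_seed: 1
n_folds: 10
fs_common: 50
synthetic:
  n_channels: 16
  n_runs: 12
  trials_per_run: 30
  trial_duration_s: 10
  volumes_per_run: 150
  tr_s: 2
  hrf_delay_s: 6
  bold_noise_sd: 1
  control_coupling: 0.15
  coupling_exponent: 2
model:
  n_channels: 16
  n_branches: 4
  temporal_kernel: 51
  encoder_channels: 32
  pool_stride: 8
  dropout_rate: 0.3
  decoder_channel_reduction: 4
train:
  learning_rate: 3.0e-3
  weight_decay: 3.0e-4
  batch_size: 4
  scheduler_t_max_epochs: 40
  early_stop_patience_epochs: 20
  max_epochs: 40
  windows_per_epoch: 16
  window_s: 160
  compact_lr_mult: 0.02
  tail_average_epochs: 12
loss:
  weight_mse: 0.9
  weight_corr: 0.1
evaluation:
  n_surrogates: 200
  alpha: 0.05
  rois: [VC, PMC, STN]
interpret:
  k_top: 3
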