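# Example configuration for the bindsite command-line interface.
# Every value below is the package default.

network:
  k: 5              # convolution kernel width (odd)
  n_blocks: 10      # BasicBlocks per encoder stage (N)
  m_blocks: 2       # blocks per context stage of the enhanced decoder (M)
  channels: 256     # channel half-width c (blocks carry 2c = 512 channels)
  d: 30             # input feature dimensions
  dropout_rate: 0.5
  mode: std         # std | en
  n_stages: 2       # encoder stages

training:
  gamma: 0.2        # L2 coefficient on convolution/projection kernels
  dropout_rate: 0.5
  batch_size: 4
  optimizer: sgd    # sgd | adam
  reduction: mean   # mean | sum
  seed: 1
  stages:           # three-stage learning schedule: preheat / escape / finish
    - {init: 0.05, decay: 0.9, interval: 100, budget: 300}
    - {init: 0.15, decay: 0.9, interval: 100, budget: 900}
    - {init: 0.02, decay: 0.8, interval: 100, budget: 300}

simulation:
  n_proteins: 100
  length_range: [80, 300]
  pos_fraction: 0.03   # target binding-residue fraction
  motif_weight: 0.5
  pair_weight: 0.5
  pair_distance: 4
  snr_pssm: 2
  snr_cs: 1
  clustering: 3        # mean planted positive-run length
  seed: 1

predict:
  threshold: 0.4       # minimum positive-class probability to call binding
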