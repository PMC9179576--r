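# Desk-scale experiment profile: 80 synthetic patients, 32 px images,
# small CNN, 20 pretext + 25 development epochs. Keys mirror
# rccgrade::experiment_config().
seed: 1
synth:
  n_patients: 80
  high_fraction: 0.4
  noise_rate_true: 0.4
  images_per_patient_range: [10, 25]
  image_size_range: [24, 96]
input_edge: 32
pretext_epochs: 20
develop_epochs: 25
warmup_epochs: 5
base_lr: 0.1
backbone_lr_ratio: 0.1
weight_decay: 0.0001
batch_size: 32
alpha: 0.4
class_weight_scheme: inverse_frequency
threshold: 0.5
cells: [base, ssl, loss, full]
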