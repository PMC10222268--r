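# Example simulator configuration: 2 subjects, 6 channels, two classes
# separated by burst frequency on channels 2 and 4.
n_subjects: 2
n_channels: 6
n_trials_per_class: 12
n_classes: 2
fs: 64
n_samples: 64
noise_sd: 0.8
alpha_amplitude: 0.3
amp_jitter_sd: 0.1
latency_jitter_sd: 0.01
seed: 42
bursts:
  - {class: 1, channel: 2, freq: 6,  latency: 0.30, duration: 0.4, amplitude: 2.5}
  - {class: 1, channel: 4, freq: 6,  latency: 0.30, duration: 0.4, amplitude: 2.5}
  - {class: 2, channel: 2, freq: 10, latency: 0.35, duration: 0.4, amplitude: 2.5}
  - {class: 2, channel: 4, freq: 10, latency: 0.35, duration: 0.4, amplitude: 2.5}
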