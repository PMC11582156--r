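# Example run configuration for `uteqmt simulate --config ...`
# A 2-chip phantom with the default bone protocol.
phantom:
  chip_size: 6
  mmf: [0.30, 0.60]
  k_ab: [10.0, 60.0]
  t1_obs: [0.24, 0.24]
  t2a: [0.0008, 0.0008]
protocol:
  powers_deg: [400, 800, 1200]
  offsets_hz: [2000, 5000, 10000, 20000, 50000]
  timing:
    tr_s: 0.086
    n_spokes: 13
    inter_spoke_tr_s: 0.005
    excitation_fa_deg: 10
  pulse_duration_s: 0.008
  pulse_shape: fermi
  lineshape: gaussian
noise:
  target_snr: 100
seed: 1
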