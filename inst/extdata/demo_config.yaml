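# Demonstration pipeline configuration: stenosed femoral phantom at a
# desk-scale resolution. Units: mm, s, cm/s, mL/s.
seed: 1
synth:
  waveform:
    period: 1.0
    forward_volume: 9.6
    backflow_volume: 2.3
    n_samples: 201
  vessel:
    stenosis_area_reduction: 0.75
  field:
    grid_spacing: 0.25
    vessel_length: 30
    jet_length: 15
    stenosis_center: 10
    n_times: 8
  render:
    pixel_size: 0.15
    frame_rate: 6000
    n_frames: 10
    noise_sd: 1
piv:
  schedule:
    window_sizes: [32, 16]
    overlap: 0.5
  postprocess:
    spatial_gaussian: true
    temporal_window: 3
    temporal_mode: moving_average
analyze:
  vc: true
compare:
  against_truth: true
  scope: all_timepoints
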