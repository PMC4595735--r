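# Default acquisition geometry: 20 keV parallel beam, 5.92 um detector
# pixels, 50 cm propagation distance, 720 projections over 180 degrees,
# 963 x 1933 pixel frames captured as two vertically overlapping
# half-scans (about 200 px overlap).
geometry:
  energy_kev: 20.0
  pixel_size_um: 5.92
  distance_cm: 50
  n_angles: 720
  angular_range_deg: 180
  detector_shape: [963, 1933]
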