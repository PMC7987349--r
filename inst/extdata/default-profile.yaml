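# Default acquisition profile: 128-element 15.625-MHz linear array imaging
# through a 250-Hz resonant tilting mirror in water. At PRF 20 kHz and a
# single transmit angle the ratio PRFe/Fm = 80 is even, so the volume rate is
# 2*Fm = 500 Hz with 41 planes per volume (extremal planes shared).
seed: 1
output_dir: "planesweep-output"
acquisition:
  sound_speed_m_s: 1480        # water
  imaging_depth_mm: 28.6       # from the mirror plate centre
  prf_hz: 20000
  n_compound_angles: 1
  n_scan_lines: 1
  mirror_offset_mm: 2.1        # transducer-to-mirror distance
  duration_s: 0.012            # three tilting cycles
  snr_db: .inf                 # noiseless by default
mirror:
  half_range_deg: 11.95        # mean of the +12.6/-11.3 measured range at 10 Vpp
  tilt_freq_hz: 250            # resonance in water
  phase_rad: 0
  offset_deg: 0
transducer:
  n_elements: 128
  pitch_mm: 0.1                # 12.8-mm lateral range
  center_freq_mhz: 15.625
  sampling_freq_mhz: 62.5      # 4 samples per carrier period
  pulse_cycles: 3
  elevational_focus_mm: 6
  elevational_fwhm_mm: 0.5     # beam model waist FWHM at the focus
phantom:
  type: wires
  n_wires: 4
  spacing_mm: 3
  depth_mm: 15
  wire_length_mm: 8
  depth_jitter_mm: 0
calibration:
  duration_s: 0.04             # ten tilting cycles
  sample_rate_hz: 10000
  range_z_mm: 16.9
  angle_noise_sd_deg: 0.2
reconstruction:
  voxel_mm: 0.1
  dynamic_range_db: 40
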