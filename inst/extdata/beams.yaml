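# Synthetic beam fixtures emulating the characterized beam set: five open
# beams at isocenter and two range-shifted (RaShi) beams at 50 cm
# isocenter-to-surface distance. Beams with published core-width measurements
# carry them as anchors (growth interpolates them exactly); the remaining
# beams use the parametric power-law + drift growth with illustrative
# parameters. Halo slopes are calibrated at load time so the midrange profile
# crosses 0.1% of the central-axis dose at halo_reach_sigma core widths.
# Ranges are R80 in water (residual range for RaShi beams).
beams:
  open_62:
    label: "62.4 MeV"
    energy_mev: 62.4
    range_r80_mm: 30.7
    z0_mm: 14
    sigma0_mm: 9.09
    theta0_rad: 0.004
    mcs_scale_mm: 2.0
    mcs_exponent: 0.9
    halo_amp_floor: 0.2
    halo_amp_peak: 1.0
    halo_reach_sigma: 6.0
    rashi: false
  rashi_97:
    label: "97.4 MeV + RaShi"
    energy_mev: 97.4
    range_r80_mm: 31.0
    z0_mm: 14
    sigma0_mm: 6.50
    theta0_rad: 0.004
    mcs_scale_mm: 2.0
    mcs_exponent: 0.9
    halo_amp_floor: 0.8
    halo_amp_peak: 2.0
    halo_reach_sigma: 8.0
    rashi: true
  rashi_124:
    label: "124.7 MeV + RaShi"
    energy_mev: 124.7
    range_r80_mm: 78.0
    z0_mm: 14
    sigma0_mm: 5.50
    theta0_rad: 0.005
    mcs_scale_mm: 3.0
    mcs_exponent: 0.9
    halo_amp_floor: 0.8
    halo_amp_peak: 2.0
    halo_reach_sigma: 8.0
    rashi: true
  open_148:
    label: "148.2 MeV"
    energy_mev: 148.2
    range_r80_mm: 153.2
    z0_mm: 20
    sigma0_mm: 4.53
    halo_amp_floor: 0.2
    halo_amp_peak: 1.0
    halo_reach_sigma: 7.0
    rashi: false
    anchors:
      - {z_mm: 76.60, sigma_mm: 4.84}   # 50% R80
      - {z_mm: 122.56, sigma_mm: 5.40}  # 80% R80
      - {z_mm: 148.604, sigma_mm: 5.96} # 97% R80
  open_198:
    label: "198.0 MeV"
    energy_mev: 198.0
    range_r80_mm: 255.0
    z0_mm: 20
    sigma0_mm: 3.80
    theta0_rad: 0.008
    mcs_scale_mm: 5.0
    mcs_exponent: 1.3
    halo_amp_floor: 0.2
    halo_amp_peak: 1.0
    halo_reach_sigma: 8.5
    rashi: false
  open_252:
    label: "252.7 MeV"
    energy_mev: 252.7
    range_r80_mm: 393.0
    z0_mm: 20
    sigma0_mm: 3.17
    halo_amp_floor: 0.2
    halo_amp_peak: 1.0
    halo_reach_sigma: 10.0
    rashi: false
    anchors:
      - {z_mm: 196.50, sigma_mm: 4.31}  # 50% R80
      - {z_mm: 314.40, sigma_mm: 6.58}  # 80% R80
      - {z_mm: 381.21, sigma_mm: 8.80}  # 97% R80
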