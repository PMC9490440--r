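# Example run configuration for bioapatite::load_run_config().
# Every key is optional; omitted keys fall back to package defaults.
seed: 1
tolerance: 5            # peak search half-window, cm-1
anchors: [450, 800, 900, 1200, 1300, 1800, 2200, 3800]
detection_limits:       # oxide wt%; replace with instrument values
  K2O: 0.01
  Na2O: 0.01
  MgO: 0.01
thresholds:
  k_threshold: 0.07     # elemental K wt%
  k_band: 0.01          # borderline half-width
  fresh_floor: 0.20     # fresh-burnt K floor
  cn_p_floor: 0.02      # CN/P above this reads as burnt
  irsf_cut: 3.8         # IRSF fallback cut when CN/P is unavailable
stats:
  alternative: two.sided
  p_adjust: holm
design:
  points_per_zone: 3
low_total_fraction: 0.1173  # QC-removable rate emulated by the generator
spectrum_noise_sd: 0.004
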