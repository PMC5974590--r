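# Display and viewing geometry for a 27-inch 1920x1080 monitor.
display:
  diagonal_cm: 68.58          # or width_cm + height_cm for non-square pixels
  resolution_x: 1920
  resolution_y: 1080
  viewing_distance_cm_default: 60   # used when an export has no distance data

# I-VT fixation-filter parameters (package defaults shown).
ivt:
  velocity_threshold_deg_s: 30
  min_fixation_ms: 60
  velocity_window_ms: 20
  max_gap_ms: 75
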