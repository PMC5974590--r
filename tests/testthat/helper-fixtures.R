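# shared fixtures: canonical sample frames built in code, no files on disk

the_display <- display_model()  # 27-inch 1920x1080, square pixels

make_samples <- function(t_ms, x_px, y_px, media = "T1", fix_idx = NA_integer_,
                         dist = 60, val_l = 0L, val_r = 0L) {
  n <- length(t_ms)
  data.frame(
    t_ms = t_ms, media = rep_len(media, n),
    fix_idx = rep_len(as.integer(fix_idx), n),
    x_px = rep_len(x_px, n), y_px = rep_len(y_px, n),
    dist_l_cm = rep_len(dist, n), dist_r_cm = rep_len(dist, n),
    val_l = rep_len(as.integer(val_l), n), val_r = rep_len(as.integer(val_r), n),
    stringsAsFactors = FALSE
  )
}

# piecewise-constant gaze path in angle space: one dwell per location,
# instantaneous jumps between dwells
make_dwell_trace <- function(ax_deg, ay_deg, dur_ms, rate_hz = 300,
                             distance_cm = 60, media = "T1") {
  dt <- 1000 / rate_hz
  reps <- round(dur_ms / dt)
  ax <- rep(ax_deg, reps)
  ay <- rep(ay_deg, reps)
  xy <- angles_to_point(ax, ay, the_display, distance_cm)
  make_samples((seq_along(ax) - 1) * dt, xy[, 1], xy[, 2], media = media)
}
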