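# independent brute-force oracles; deliberately share no code with R/

# cm per pixel for a square-pixel display straight from the diagonal
oracle_pitch <- function(diagonal_cm = 27 * 2.54, rx = 1920, ry = 1080) {
  diagonal_cm / sqrt(rx^2 + ry^2)
}

oracle_axis_angles <- function(px, center_px, distance_cm,
                               pitch = oracle_pitch()) {
  vapply(px, function(p) atan2((p - center_px) * pitch, distance_cm) * 180 / pi, 0)
}

# loop-based accuracy / SD / RMS over one fixation's valid samples; the
# fixation location is the pixel-space mean of the samples, converted to
# angles for the target comparison
oracle_metrics <- function(x_px, y_px, target_x, target_y, distance_cm = 60) {
  ax <- oracle_axis_angles(x_px, 960, distance_cm)
  ay <- oracle_axis_angles(y_px, 540, distance_cm)
  n <- length(ax)
  cx <- oracle_axis_angles(sum(x_px) / n, 960, distance_cm)
  cy <- oracle_axis_angles(sum(y_px) / n, 540, distance_cm)
  tx <- oracle_axis_angles(target_x, 960, distance_cm)
  ty <- oracle_axis_angles(target_y, 540, distance_cm)
  acc <- sqrt((cx - tx)^2 + (cy - ty)^2)
  mx <- sum(ax) / n
  my <- sum(ay) / n
  ssx <- 0; ssy <- 0
  for (i in seq_len(n)) {
    ssx <- ssx + (ax[i] - mx)^2
    ssy <- ssy + (ay[i] - my)^2
  }
  dsx <- 0; dsy <- 0
  for (i in seq_len(n - 1)) {
    dsx <- dsx + (ax[i + 1] - ax[i])^2
    dsy <- dsy + (ay[i + 1] - ay[i])^2
  }
  list(accuracy = acc,
       sd = c(sqrt(ssx / n), sqrt(ssy / n)),
       rms = c(sqrt(dsx / (n - 1)), sqrt(dsy / (n - 1))))
}

# exact paired signed-rank null by enumerating all 2^n sign assignments
oracle_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  m <- n * (n + 1) / 2
  p <- if (v_obs > m / 2) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  list(V = v_obs, p = min(p, 1))
}

# Mann-Whitney U by direct pair counting
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}
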