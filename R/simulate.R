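#' Synthetic gaze-session configuration
#'
#' Generative model for one participant's calibration-verification session:
#' five targets shown for 2,000 ms each at 300 Hz (the default layout and
#' timing of the verification protocol). Per trial the simulated gaze holds
#' its previous position for a reaction latency, relocates to the target in
#' a short high-velocity saccade ramp, then dwells on the target displaced
#' by a per-participant angular calibration offset. Per-axis measurement
#' noise is Gaussian with optional lag-1 autocorrelation (first-order
#' autoregressive), which makes the two precision measures analytically
#' separable: SD depends on the marginal sigma while sample-to-sample RMS
#' equals `sigma * sqrt(2 * (1 - rho))`. Non-compliant trials replace the
#' dwell with rapid roaming over (and beyond) the screen; dropout marks
#' samples invalid.
#'
#' @param seed Integer seed; the whole session is deterministic given it.
#' @param rate_hz Sampling rate (default 300).
#' @param trial_duration_ms Trial duration (default 2000).
#' @param display,layout Display model and target layout.
#' @param distance_cm Viewing distance (written into the export's per-eye
#'   distance columns).
#' @param offset_deg Length-2 per-participant calibration offset
#'   (degrees, x and y); measured accuracy should recover its norm.
#' @param noise_sd_deg Length-2 per-axis noise sigma (degrees).
#' @param noise_ar1 Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param dropout_prob Per-sample probability of a validity loss.
#' @param trial_compliance Probability that a trial is fixated.
#' @param latency_range_ms Uniform range of the pre-saccade hold.
#' @param saccade_duration_ms Duration of the relocation ramp.
#' @param roam_dwell_range_ms Uniform range of roaming mini-dwells during
#'   non-compliant trials (below the minimum fixation duration, so roaming
#'   yields no valid fixations).
#' @param participant_id Identifier written into the export.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, rate_hz = 300, trial_duration_ms = 2000,
                              display = display_model(),
                              layout = default_target_layout(display),
                              distance_cm = 60,
                              offset_deg = c(0, 0),
                              noise_sd_deg = c(0.1, 0.15),
                              noise_ar1 = 0.3,
                              dropout_prob = 0.02,
                              trial_compliance = 1,
                              latency_range_ms = c(100, 300),
                              saccade_duration_ms = 30,
                              roam_dwell_range_ms = c(25, 50),
                              participant_id = "sim") {
  stopifnot(rate_hz > 0, trial_duration_ms > 0, length(offset_deg) == 2,
            length(noise_sd_deg) == 2, all(noise_sd_deg >= 0),
            dropout_prob >= 0, dropout_prob <= 1,
            trial_compliance >= 0, trial_compliance <= 1)
  if (noise_ar1 < 0 || noise_ar1 >= 1) {
    stop("noise_ar1 must lie in [0, 1) for a stationary noise process", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), rate_hz = rate_hz,
         trial_duration_ms = trial_duration_ms, display = display,
         layout = layout, distance_cm = distance_cm,
         offset_deg = as.numeric(offset_deg),
         noise_sd_deg = as.numeric(noise_sd_deg), noise_ar1 = noise_ar1,
         dropout_prob = dropout_prob, trial_compliance = trial_compliance,
         latency_range_ms = latency_range_ms,
         saccade_duration_ms = saccade_duration_ms,
         roam_dwell_range_ms = roam_dwell_range_ms,
         participant_id = participant_id),
    class = "simulation_config"
  )
}

ar1_noise <- function(n, sd, rho) {
  if (n == 0L) return(numeric())
  if (sd == 0) return(rep(0, n))
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- sd * z[1]
  if (n > 1L) {
    innov <- sd * sqrt(1 - rho^2) * z[-1]
    for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
  }
  e
}

#' Simulate one participant's verification session
#'
#' Deterministic given `cfg$seed`. Targets appear in pseudorandom order with
#' the center target never first. Returns the recording in the canonical
#' export dialect (re-readable via [write_gaze_export()] /
#' [read_gaze_export()]) together with the ground truth a correct pipeline
#' should recover.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `recording` (a [gaze_recording()]) and
#'   `truth`: `target_order`, `trials` (per-trial target, onset/offset,
#'   compliance flag and intended dwell interval/location), `episodes`
#'   (every constant-position hold or dwell, merged across contiguous
#'   same-position spans), `offset_deg`, `noise_sd_deg`, `noise_ar1`,
#'   `dropout_prob`, `distance_cm`, and `n_dropout`.
#' @export
simulate_participant <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  display <- cfg$display
  layout <- cfg$layout
  d <- cfg$distance_cm
  dt <- 1000 / cfg$rate_hz
  dur <- cfg$trial_duration_ms
  n_trials <- nrow(layout)

  ids <- layout$target_id
  ord <- sample(ids)
  if (ord[1] == "center" && n_trials > 1L) {
    j <- sample(2:n_trials, 1L)
    ord[c(1, j)] <- ord[c(j, 1)]
  }
  tgt_ang <- point_angles(layout$x_px, layout$y_px, display, d)
  rownames(tgt_ang) <- layout$target_id

  n_per <- round(dur / dt)
  n <- n_per * n_trials
  t_ms <- (seq_len(n) - 1) * dt
  media <- rep(ord, each = n_per)

  ax <- numeric(n); ay <- numeric(n)
  cur <- c(0, 0)  # gaze starts at screen center
  episodes <- list()
  add_episode <- function(kind, loc, start, end) {
    episodes[[length(episodes) + 1L]] <<- data.frame(
      kind = kind, ax_deg = loc[1], ay_deg = loc[2],
      start_ms = start, end_ms = end, stringsAsFactors = FALSE)
  }
  trials <- data.frame(trial = seq_len(n_trials), target_id = ord,
                       onset_ms = (seq_len(n_trials) - 1) * dur,
                       offset_ms = seq_len(n_trials) * dur,
                       compliant = NA, dwell_start_ms = NA_real_,
                       dwell_end_ms = NA_real_, dwell_ax_deg = NA_real_,
                       dwell_ay_deg = NA_real_, stringsAsFactors = FALSE)

  for (k in seq_len(n_trials)) {
    i0 <- (k - 1) * n_per
    onset <- trials$onset_ms[k]
    compliant <- stats::runif(1) < cfg$trial_compliance
    trials$compliant[k] <- compliant
    if (compliant) {
      dwell <- tgt_ang[ord[k], ] + cfg$offset_deg
      lat <- stats::runif(1, cfg$latency_range_ms[1], cfg$latency_range_ms[2])
      sac <- cfg$saccade_duration_ms
      rel <- t_ms[(i0 + 1):(i0 + n_per)] - onset
      hold_i <- rel < lat
      ramp_i <- rel >= lat & rel < lat + sac
      dwell_i <- rel >= lat + sac
      ax[i0 + which(hold_i)] <- cur[1]; ay[i0 + which(hold_i)] <- cur[2]
      frac <- (rel[ramp_i] - lat) / sac
      ax[i0 + which(ramp_i)] <- cur[1] + frac * (dwell[1] - cur[1])
      ay[i0 + which(ramp_i)] <- cur[2] + frac * (dwell[2] - cur[2])
      ax[i0 + which(dwell_i)] <- dwell[1]; ay[i0 + which(dwell_i)] <- dwell[2]
      add_episode("hold", cur, onset, onset + lat)
      add_episode("dwell", dwell, onset + lat + sac, onset + dur)
      trials$dwell_start_ms[k] <- onset + lat + sac
      trials$dwell_end_ms[k] <- onset + dur
      trials$dwell_ax_deg[k] <- dwell[1]; trials$dwell_ay_deg[k] <- dwell[2]
      cur <- dwell
    } else {
      # rapid scanning: mini-dwells too short to classify as fixations,
      # occasionally beyond the screen edge
      ext_x <- px_offset_to_deg(display$resolution_x / 2, display, d)
      ext_y <- px_offset_to_deg(display$resolution_y / 2, display, d, axis = "y")
      left <- dur
      pos_ms <- 0
      while (left > 1e-9) {
        hold <- min(stats::runif(1, cfg$roam_dwell_range_ms[1],
                                 cfg$roam_dwell_range_ms[2]), left)
        loc <- c(stats::runif(1, -ext_x - 3, ext_x + 3),
                 stats::runif(1, -ext_y - 3, ext_y + 3))
        rel <- t_ms[(i0 + 1):(i0 + n_per)] - onset
        in_i <- rel >= pos_ms & rel < pos_ms + hold
        ax[i0 + which(in_i)] <- loc[1]; ay[i0 + which(in_i)] <- loc[2]
        add_episode("roam", loc, onset + pos_ms, onset + pos_ms + hold)
        cur <- loc
        pos_ms <- pos_ms + hold
        left <- left - hold
      }
    }
  }

  ax <- ax + ar1_noise(n, cfg$noise_sd_deg[1], cfg$noise_ar1)
  ay <- ay + ar1_noise(n, cfg$noise_sd_deg[2], cfg$noise_ar1)
  xy <- angles_to_point(ax, ay, display, d)

  drop <- stats::runif(n) < cfg$dropout_prob
  samples <- data.frame(
    t_ms = t_ms, media = media, fix_idx = rep(NA_integer_, n),
    x_px = ifelse(drop, NA_real_, xy[, 1]),
    y_px = ifelse(drop, NA_real_, xy[, 2]),
    dist_l_cm = rep(d, n), dist_r_cm = rep(d, n),
    val_l = ifelse(drop, 4L, 0L), val_r = ifelse(drop, 4L, 0L),
    stringsAsFactors = FALSE
  )

  ep <- do.call(rbind, episodes)
  # merge contiguous same-position episodes (a dwell continuing into the
  # next trial's pre-saccade hold is one constant-position span)
  if (nrow(ep) > 1L) {
    keep <- rep(TRUE, nrow(ep))
    for (i in 2:nrow(ep)) {
      j <- max(which(keep[1:(i - 1)]))
      same_loc <- isTRUE(all.equal(c(ep$ax_deg[j], ep$ay_deg[j]),
                                   c(ep$ax_deg[i], ep$ay_deg[i]), tolerance = 1e-9))
      contiguous <- abs(ep$end_ms[j] - ep$start_ms[i]) < dt
      if (same_loc && contiguous) {
        ep$end_ms[j] <- ep$end_ms[i]
        keep[i] <- FALSE
      }
    }
    ep <- ep[keep, , drop = FALSE]
    rownames(ep) <- NULL
  }
  ep$duration_ms <- ep$end_ms - ep$start_ms

  list(
    recording = gaze_recording(cfg$participant_id, samples, cfg$rate_hz),
    truth = list(target_order = ord, trials = trials, episodes = ep,
                 offset_deg = cfg$offset_deg, noise_sd_deg = cfg$noise_sd_deg,
                 noise_ar1 = cfg$noise_ar1, dropout_prob = cfg$dropout_prob,
                 distance_cm = d, n_dropout = sum(drop))
  )
}

#' Cohort presets
#'
#' Generative parameters for four participant groups, ordered so that
#' adult offset/noise < school-age < toddler and toddler compliance < 1.
#' Magnitudes are calibrated to reproduce the qualitative ordering of group
#' data quality seen in developmental samples, not any specific dataset:
#' per-participant calibration-offset magnitudes are lognormal around
#' `offset_mean_deg` (coefficient of variation `offset_cv`) with uniform
#' direction; per-axis noise sigmas get a mild lognormal jitter
#' (`noise_cv`). `session_compliance` is the probability that a participant
#' engages with the task at all — a non-engaged toddler produces roaming
#' gaze on every trial and ends up excluded for having no valid fixations.
#'
#' @param preset One of `"adult"`, `"school_age"`, `"toddler_18m"`,
#'   `"toddler_30m"`.
#' @return Named list of preset parameters.
#' @export
cohort_preset <- function(preset = c("adult", "school_age", "toddler_18m",
                                     "toddler_30m")) {
  preset <- match.arg(preset)
  presets <- list(
    adult = list(offset_mean_deg = 0.6, offset_cv = 0.3,
                 noise_sd_deg = c(0.10, 0.15), noise_cv = 0.1, noise_ar1 = 0.35,
                 dropout_prob = 0.02, trial_compliance = 1.0,
                 session_compliance = 1.0, distance_cm = 64.6, distance_sd_cm = 2),
    school_age = list(offset_mean_deg = 1.0, offset_cv = 0.3,
                 noise_sd_deg = c(0.14, 0.19), noise_cv = 0.1, noise_ar1 = 0.35,
                 dropout_prob = 0.05, trial_compliance = 0.95,
                 session_compliance = 1.0, distance_cm = 64.2, distance_sd_cm = 2),
    toddler_18m = list(offset_mean_deg = 1.5, offset_cv = 0.3,
                 noise_sd_deg = c(0.19, 0.22), noise_cv = 0.1, noise_ar1 = 0.45,
                 dropout_prob = 0.12, trial_compliance = 0.80,
                 session_compliance = 0.78, distance_cm = 62.0, distance_sd_cm = 3),
    toddler_30m = list(offset_mean_deg = 1.45, offset_cv = 0.3,
                 noise_sd_deg = c(0.18, 0.21), noise_cv = 0.1, noise_ar1 = 0.45,
                 dropout_prob = 0.10, trial_compliance = 0.85,
                 session_compliance = 0.86, distance_cm = 62.0, distance_sd_cm = 3)
  )
  c(list(preset = preset), presets[[preset]])
}

#' Simulate a cohort of participants
#'
#' Draws per-participant parameters from a [cohort_preset()], simulates each
#' session with a deterministically derived sub-seed (cohorts are
#' reproducible regardless of generation order), and optionally writes a
#' study directory: one tab-separated export per participant plus a
#' `manifest.tsv` recording the ground-truth parameters.
#'
#' @param preset Preset name, see [cohort_preset()].
#' @param n Number of participants.
#' @param seed Master seed.
#' @param dir Output directory for exports and manifest, or `NULL` to keep
#'   the cohort in memory only.
#' @param overrides Named list overriding preset fields (e.g.
#'   `list(offset_cv = 0, offset_mean_deg = 1)` for a fixed injected
#'   offset).
#' @param display,layout Geometry shared by all participants.
#' @return List of class `sim_cohort`: `participants` (each a
#'   [simulate_participant()] result plus its `config`), `manifest` (data
#'   frame), `preset`, `dir`.
#' @export
simulate_cohort <- function(preset = "adult", n = 10, seed = 1L, dir = NULL,
                            overrides = list(), display = display_model(),
                            layout = default_target_layout(display)) {
  stopifnot(n >= 1)
  pp <- cohort_preset(preset)
  pp[names(overrides)] <- overrides
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  sdlog <- sqrt(log(1 + pp$offset_cv^2))
  mags <- stats::rlnorm(n, log(pp$offset_mean_deg) - sdlog^2 / 2, sdlog)
  dirs <- stats::runif(n, 0, 2 * pi)
  nslog <- sqrt(log(1 + pp$noise_cv^2))
  noise_mult <- stats::rlnorm(n, -nslog^2 / 2, nslog)
  engaged <- stats::runif(n) < pp$session_compliance
  distances <- pmax(stats::rnorm(n, pp$distance_cm, pp$distance_sd_cm), 40)

  participants <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("%s_%03d", pp$preset, i)
    cfg <- simulation_config(
      seed = sub_seeds[i], display = display, layout = layout,
      distance_cm = distances[i],
      offset_deg = mags[i] * c(cos(dirs[i]), sin(dirs[i])),
      noise_sd_deg = pp$noise_sd_deg * noise_mult[i],
      noise_ar1 = pp$noise_ar1, dropout_prob = pp$dropout_prob,
      trial_compliance = if (engaged[i]) pp$trial_compliance else 0,
      participant_id = pid
    )
    sim <- simulate_participant(cfg)
    sim$config <- cfg
    participants[[i]] <- sim
    manifest[[i]] <- data.frame(
      participant = pid, seed = sub_seeds[i],
      offset_x_deg = cfg$offset_deg[1], offset_y_deg = cfg$offset_deg[2],
      offset_mag_deg = mags[i],
      noise_sd_x_deg = cfg$noise_sd_deg[1], noise_sd_y_deg = cfg$noise_sd_deg[2],
      noise_ar1 = cfg$noise_ar1, dropout_prob = cfg$dropout_prob,
      trial_compliance = cfg$trial_compliance, engaged = engaged[i],
      distance_cm = distances[i], stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_gaze_export(participants[[i]]$recording,
                        file.path(dir, paste0(manifest$participant[i], ".tsv")))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  structure(list(participants = participants, manifest = manifest,
                 preset = pp$preset, dir = dir),
            class = "sim_cohort")
}

#' Analytic expectations for the simulator's quality metrics
#'
#' For a stationary configuration (full compliance, constant offset, AR(1)
#' noise): expected accuracy in the noise-free limit is the offset norm;
#' expected per-axis SD precision is `sigma * sqrt(1 - Var(mean)/sigma^2)`
#' with the exact AR(1) small-sample correction for a fixation of
#' `n_samples` samples; expected per-axis RMS precision is
#' `sigma * sqrt(2 * (1 - rho))`. As `rho` grows toward 1 the noise becomes
#' a smooth drift: RMS falls toward 0 while SD stays near sigma — exactly
#' the distinction the two precision measures probe.
#'
#' @param cfg A [simulation_config()].
#' @param n_samples Number of samples in the fixation the SD correction
#'   refers to; default is the samples in one full trial.
#' @return List with `accuracy_deg`, `sd_deg` (length 2), `rms_deg`
#'   (length 2).
#' @export
expected_metrics <- function(cfg, n_samples = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  rho <- cfg$noise_ar1
  if (rho < 0 || rho >= 1) {
    stop("unsupported config: expectations require stationary noise (0 <= rho < 1)",
         call. = FALSE)
  }
  if (is.null(n_samples)) {
    n_samples <- round(cfg$trial_duration_ms * cfg$rate_hz / 1000)
  }
  n <- n_samples
  # Var of the mean of n AR(1) samples with marginal variance sigma^2
  k <- seq_len(n - 1)
  var_mean_factor <- (1 + 2 * sum((1 - k / n) * rho^k)) / n
  sd_factor <- sqrt(max(1 - var_mean_factor, 0))
  list(
    accuracy_deg = sqrt(sum(cfg$offset_deg^2)),
    sd_deg = cfg$noise_sd_deg * sd_factor,
    rms_deg = cfg$noise_sd_deg * sqrt(2 * (1 - rho))
  )
}
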