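#' I-VT fixation-filter parameters
#'
#' Velocity-threshold (I-VT) classification: samples whose angular speed
#' stays below `velocity_threshold_deg_s` form fixation candidates; runs
#' shorter than `min_fixation_ms` are discarded. Defaults follow the common
#' verification setup: 30 deg/s threshold and 60 ms minimum duration.
#'
#' `velocity_window_ms` is the width of the centered window over which speed
#' is measured (20 ms, about 7 samples at 300 Hz, suppresses single-sample
#' noise spikes). `max_gap_ms` is the longest invalid gap (blink/dropout)
#' bridged inside a fixation, with no interpolation. Adjacent fixation
#' fragments separated by no more than `max_gap_ms` whose centroids lie
#' within `merge_max_angle_deg` are merged, mirroring the merge step of
#' vendor I-VT implementations; a large-angle jump between dwells is never
#' merged.
#'
#' @param velocity_threshold_deg_s Angular speed threshold (deg/s). A sample
#'   exactly at threshold is non-fixation (strict `<`).
#' @param min_fixation_ms Minimum fixation duration (ms).
#' @param velocity_window_ms Centered velocity-estimation window (ms).
#' @param max_gap_ms Maximum bridged gap (ms).
#' @param merge_max_angle_deg Maximum centroid separation for merging
#'   adjacent fixation fragments (deg).
#' @return An object of class `ivt_params`.
#' @export
ivt_params <- function(velocity_threshold_deg_s = 30, min_fixation_ms = 60,
                       velocity_window_ms = 20, max_gap_ms = 75,
                       merge_max_angle_deg = 0.5) {
  vals <- c(velocity_threshold_deg_s, min_fixation_ms, velocity_window_ms, max_gap_ms)
  if (any(!is.finite(vals)) || any(vals <= 0) || merge_max_angle_deg < 0) {
    stop("ivt_params: all parameters must be strictly positive", call. = FALSE)
  }
  structure(
    list(velocity_threshold_deg_s = velocity_threshold_deg_s,
         min_fixation_ms = min_fixation_ms,
         velocity_window_ms = velocity_window_ms,
         max_gap_ms = max_gap_ms,
         merge_max_angle_deg = merge_max_angle_deg),
    class = "ivt_params"
  )
}

#' Per-sample angular speed
#'
#' Speed at each sample is the angular separation between the first and last
#' valid samples of a centered window of width `velocity_window_ms`, divided
#' by their time span. Undefined (`NA`) where the window contains an invalid
#' sample or fewer than two samples.
#'
#' @param samples Canonical samples data frame.
#' @param display A [display_model()].
#' @param distance_cm Viewing distance in cm.
#' @param params An [ivt_params()].
#' @param valid Optional logical vector from [sample_is_valid()]; computed
#'   with the default policy if omitted.
#' @return Numeric vector of speeds in deg/s, `NA` where undefined.
#' @export
angular_velocity <- function(samples, display, distance_cm, params = ivt_params(),
                             valid = NULL) {
  if (inherits(samples, "gaze_recording")) samples <- samples$samples
  if (is.null(valid)) valid <- sample_is_valid(samples, display)
  n <- nrow(samples)
  if (sum(valid) < 2L) return(rep(NA_real_, n))
  t <- samples$t_ms
  ang <- matrix(NA_real_, n, 2)
  ang[valid, ] <- point_angles(samples$x_px[valid], samples$y_px[valid],
                               display, distance_cm)
  half <- params$velocity_window_ms / 2
  j0 <- findInterval(t - half, t, left.open = TRUE) + 1L
  j1 <- findInterval(t + half, t)
  n_invalid <- cumsum(!valid)
  any_invalid <- (n_invalid[j1] - n_invalid[j0] + !valid[j0]) > 0
  span_ms <- t[j1] - t[j0]
  sep <- sqrt((ang[j1, 1] - ang[j0, 1])^2 + (ang[j1, 2] - ang[j0, 2])^2)
  speed <- sep / (span_ms / 1000)
  speed[any_invalid | j1 <= j0 | !valid] <- NA_real_
  speed
}

new_fixation_frame <- function() {
  out <- data.frame(fixation_id = integer(), start_ms = numeric(),
                    end_ms = numeric(), duration_ms = numeric(),
                    n_samples = integer(), n_valid = integer(),
                    centroid_x = numeric(), centroid_y = numeric(),
                    stringsAsFactors = FALSE)
  out$sample_idx <- list()
  out
}

build_fixation_frame <- function(groups, samples) {
  if (!length(groups)) return(new_fixation_frame())
  out <- data.frame(
    fixation_id = seq_along(groups),
    start_ms = vapply(groups, function(i) samples$t_ms[i[1]], 0),
    end_ms = vapply(groups, function(i) samples$t_ms[i[length(i)]], 0),
    n_samples = lengths(groups),
    n_valid = lengths(groups),
    centroid_x = vapply(groups, function(i) mean(samples$x_px[i]), 0),
    centroid_y = vapply(groups, function(i) mean(samples$y_px[i]), 0),
    stringsAsFactors = FALSE
  )
  out$duration_ms <- out$end_ms - out$start_ms
  out$sample_idx <- groups
  out[, c("fixation_id", "start_ms", "end_ms", "duration_ms",
          "n_samples", "n_valid", "centroid_x", "centroid_y", "sample_idx")]
}

#' Classify fixations with the I-VT filter
#'
#' Maximal runs of valid samples with angular speed strictly below the
#' threshold form fixation candidates. Invalid (or velocity-undefined) gaps
#' of at most `max_gap_ms` are bridged; gap samples contribute nothing to
#' the centroid. Adjacent candidate fragments closer than `max_gap_ms` in
#' time and `merge_max_angle_deg` in centroid separation are merged. Events
#' shorter than `min_fixation_ms` are then discarded. Above-threshold
#' samples are left unclassified (saccade/unclassified); no saccade events
#' are emitted.
#'
#' @inheritParams angular_velocity
#' @param accept_codes Validity codes accepted by [sample_is_valid()].
#' @return A fixation data frame: `fixation_id`, `start_ms`, `end_ms`,
#'   `duration_ms`, `n_samples`, `n_valid`, `centroid_x`, `centroid_y`, and
#'   the list column `sample_idx` holding the row indices (into `samples`)
#'   of each event's retained valid samples.
#' @export
classify_fixations <- function(samples, display, distance_cm,
                               params = ivt_params(), accept_codes = 0L) {
  if (inherits(samples, "gaze_recording")) samples <- samples$samples
  valid <- sample_is_valid(samples, display, accept_codes)
  speed <- angular_velocity(samples, display, distance_cm, params, valid)
  t <- samples$t_ms
  is_fix <- valid & !is.na(speed) & speed < params$velocity_threshold_deg_s
  is_sac <- valid & !is.na(speed) & speed >= params$velocity_threshold_deg_s
  fix_idx <- which(is_fix)
  if (!length(fix_idx)) return(new_fixation_frame())

  # split candidate samples into raw runs: a saccade sample or a gap longer
  # than max_gap_ms between consecutive candidates ends the run; bridging
  # across skipped samples additionally requires the gaze not to have moved
  # (a blink should resume near where it started)
  groups <- list()
  cur <- fix_idx[1]
  if (length(fix_idx) > 1L) {
    sac_cum <- cumsum(is_sac)
    for (k in 2:length(fix_idx)) {
      i_prev <- cur[length(cur)]
      i <- fix_idx[k]
      gap_ms <- t[i] - t[i_prev]
      sac_between <- sac_cum[i - 1L] - sac_cum[i_prev] > 0
      moved <- if (i - i_prev > 1L) {
        angular_separation(c(samples$x_px[i_prev], samples$y_px[i_prev]),
                           c(samples$x_px[i], samples$y_px[i]),
                           display, distance_cm) > params$merge_max_angle_deg
      } else FALSE
      if (!sac_between && !moved && gap_ms <= params$max_gap_ms) {
        cur <- c(cur, i)
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- i
      }
    }
  }
  groups[[length(groups) + 1L]] <- cur

  # vendor-style merge of adjacent fragments: close in time and in space
  merged <- list(groups[[1]])
  if (length(groups) > 1L) {
    for (k in 2:length(groups)) {
      prev <- merged[[length(merged)]]
      nxt <- groups[[k]]
      gap_ms <- t[nxt[1]] - t[prev[length(prev)]]
      cen_prev <- c(mean(samples$x_px[prev]), mean(samples$y_px[prev]))
      cen_nxt <- c(mean(samples$x_px[nxt]), mean(samples$y_px[nxt]))
      sep <- angular_separation(cen_prev, cen_nxt, display, distance_cm)
      if (gap_ms <= params$max_gap_ms && sep <= params$merge_max_angle_deg) {
        merged[[length(merged)]] <- c(prev, nxt)
      } else {
        merged[[length(merged) + 1L]] <- nxt
      }
    }
  }

  out <- build_fixation_frame(merged, samples)
  out <- out[out$duration_ms >= params$min_fixation_ms, , drop = FALSE]
  out$fixation_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Adopt fixation events from an export's fixation-index column
#'
#' Builds one fixation event per distinct exported fixation index. Invalid
#' samples inside an event (off-screen, missing, or failing the validity
#' policy) are discarded from the centroid and from the retained sample set;
#' event start/end span all samples carrying the index.
#'
#' @param recording A [gaze_recording()] whose samples carry `fix_idx`.
#' @param display A [display_model()].
#' @param accept_codes Validity codes accepted by [sample_is_valid()].
#' @return A fixation data frame as in [classify_fixations()]. Events whose
#'   samples are all invalid are kept with `n_valid = 0` and `NA` centroid.
#' @export
adopt_exported_fixations <- function(recording, display, accept_codes = 0L) {
  s <- recording$samples
  has_idx <- !is.na(s$fix_idx)
  if (!any(has_idx)) {
    stop("no fixation indices in export; use classify_fixations()", call. = FALSE)
  }
  valid <- sample_is_valid(s, display, accept_codes)
  idx_vals <- sort(unique(s$fix_idx[has_idx]))
  # non-contiguous blocks sharing an index are merged per index, with warning
  runs <- rle(ifelse(has_idx, s$fix_idx, NA_integer_))
  run_counts <- table(runs$values[!is.na(runs$values)])
  if (any(run_counts > 1)) {
    warning(sprintf("fixation index(es) %s appear in non-contiguous blocks; merged",
                    paste(names(run_counts)[run_counts > 1], collapse = ", ")),
            call. = FALSE)
  }
  rows <- split(which(has_idx), s$fix_idx[has_idx])
  rows <- rows[as.character(idx_vals)]
  out <- data.frame(
    fixation_id = idx_vals,
    start_ms = vapply(rows, function(i) min(s$t_ms[i]), 0),
    end_ms = vapply(rows, function(i) max(s$t_ms[i]), 0),
    n_samples = lengths(rows),
    stringsAsFactors = FALSE
  )
  out$duration_ms <- out$end_ms - out$start_ms
  kept <- lapply(rows, function(i) i[valid[i]])
  out$n_valid <- lengths(kept)
  out$centroid_x <- vapply(kept, function(i) if (length(i)) mean(s$x_px[i]) else NA_real_, 0)
  out$centroid_y <- vapply(kept, function(i) if (length(i)) mean(s$y_px[i]) else NA_real_, 0)
  out$sample_idx <- kept
  rownames(out) <- NULL
  out[, c("fixation_id", "start_ms", "end_ms", "duration_ms",
          "n_samples", "n_valid", "centroid_x", "centroid_y", "sample_idx")]
}

#' Fixation events for a recording, from export indices or I-VT
#'
#' Uses the export's fixation-index column when present; otherwise falls
#' back to [classify_fixations()] with the given parameters.
#'
#' @inheritParams adopt_exported_fixations
#' @param distance_cm Viewing distance in cm (used by the I-VT fallback).
#' @param params An [ivt_params()].
#' @return A fixation data frame.
#' @export
participant_fixations <- function(recording, display, distance_cm,
                                  params = ivt_params(), accept_codes = 0L) {
  if (any(!is.na(recording$samples$fix_idx))) {
    adopt_exported_fixations(recording, display, accept_codes)
  } else {
    classify_fixations(recording$samples, display, distance_cm, params, accept_codes)
  }
}
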