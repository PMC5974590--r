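#' Build a single fixation event directly from samples
#'
#' Convenience constructor for computing metrics on a known stable window
#' (e.g. simulated dwells) without running the I-VT classifier: all valid
#' samples form one event.
#'
#' @param samples Canonical samples data frame.
#' @param display A [display_model()].
#' @param accept_codes Validity codes accepted by [sample_is_valid()].
#' @return A one-row fixation data frame as in [classify_fixations()].
#' @export
fixation_from_samples <- function(samples, display, accept_codes = 0L) {
  valid <- which(sample_is_valid(samples, display, accept_codes))
  if (!length(valid)) stop("no valid samples", call. = FALSE)
  out <- build_fixation_frame(list(valid), samples)
  out$n_samples <- nrow(samples)
  out
}

#' Select the longest valid fixation of a trial
#'
#' The longest fixation on a trial is taken as the one intended to land on
#' the target. Eligible events must start at or after trial onset (and, when
#' `offset_ms` is given, before trial offset, so events belong to the trial)
#' and contain at least one valid sample; an event that continues past trial
#' offset is eligible in full. Ties on duration break to the earliest event.
#'
#' @param fixations Fixation data frame ([classify_fixations()] etc.).
#' @param onset_ms Trial onset (ms).
#' @param offset_ms Optional trial offset (ms); events starting at or after
#'   it belong to a later trial.
#' @return One-row fixation data frame, or `NULL` if no eligible event.
#' @export
select_longest_valid_fixation <- function(fixations, onset_ms, offset_ms = NULL) {
  ok <- fixations$start_ms >= onset_ms & fixations$n_valid >= 1L
  if (!is.null(offset_ms)) ok <- ok & fixations$start_ms < offset_ms
  if (!any(ok)) return(NULL)
  cand <- fixations[ok, , drop = FALSE]
  cand <- cand[order(-cand$duration_ms, cand$start_ms), , drop = FALSE]
  cand[1, , drop = FALSE]
}

fixation_axis_angles <- function(fixation, samples, display, distance_cm) {
  idx <- fixation$sample_idx[[1]]
  point_angles(samples$x_px[idx], samples$y_px[idx], display, distance_cm)
}

#' Trial accuracy: angular offset of the fixation from the target
#'
#' Euclidean distance, in degrees of visual angle, between the fixation
#' centroid (mean location of its valid samples) and the target center,
#' under the per-axis angular convention of [angular_separation()].
#'
#' @param fixation One-row fixation data frame with at least one valid sample.
#' @param target_xy Target center, `c(x_px, y_px)`.
#' @param display A [display_model()].
#' @param distance_cm Participant's mean viewing distance in cm.
#' @return Accuracy in degrees (non-negative).
#' @export
trial_accuracy <- function(fixation, target_xy, display, distance_cm) {
  if (is.null(fixation) || fixation$n_valid < 1L) {
    stop("fixation must contain at least one valid sample", call. = FALSE)
  }
  as.numeric(angular_separation(
    c(fixation$centroid_x, fixation$centroid_y), target_xy, display, distance_cm))
}

#' SD precision of a fixation, per axis
#'
#' Root-mean squared angular deviation of the fixation's valid samples from
#' their mean location, computed per axis (horizontal, vertical) with
#' population (1/n) normalisation. Each sample's pixel coordinate is
#' converted to an angle first, then deviations are taken in angle space.
#'
#' @inheritParams trial_accuracy
#' @param samples Canonical samples data frame the fixation indexes into.
#' @return Named numeric `c(sd_x = , sd_y = )` in degrees; both `NA` with a
#'   `reason` attribute when the fixation has fewer than 2 valid samples.
#' @export
precision_sd <- function(fixation, samples, display, distance_cm) {
  if (is.null(fixation) || fixation$n_valid < 2L) {
    return(structure(c(sd_x = NA_real_, sd_y = NA_real_),
                     reason = "fewer than 2 valid samples"))
  }
  a <- fixation_axis_angles(fixation, samples, display, distance_cm)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  c(sd_x = pop_sd(a[, 1]), sd_y = pop_sd(a[, 2]))
}

#' Sample-to-sample RMS precision of a fixation, per axis
#'
#' Root-mean squared angular difference between successive valid samples
#' within the single fixation (n - 1 differences for n samples), per axis.
#' "Successive" means adjacent in the retained valid-sample order: a pair
#' straddling a discarded invalid sample is still treated as adjacent, and
#' the number of such bridged pairs is reported in the `n_bridged_pairs`
#' attribute as a diagnostic.
#'
#' @inheritParams precision_sd
#' @return Named numeric `c(rms_x = , rms_y = )` in degrees with attribute
#'   `n_bridged_pairs`; both `NA` with a `reason` attribute when the
#'   fixation has fewer than 2 valid samples.
#' @export
precision_rms <- function(fixation, samples, display, distance_cm) {
  if (is.null(fixation) || fixation$n_valid < 2L) {
    return(structure(c(rms_x = NA_real_, rms_y = NA_real_),
                     reason = "fewer than 2 valid samples"))
  }
  a <- fixation_axis_angles(fixation, samples, display, distance_cm)
  idx <- fixation$sample_idx[[1]]
  rms <- function(v) sqrt(mean(diff(v)^2))
  structure(c(rms_x = rms(a[, 1]), rms_y = rms(a[, 2])),
            n_bridged_pairs = sum(diff(idx) > 1L))
}

#' Per-trial quality table for one participant
#'
#' Runs the full per-participant pipeline: validity flagging, fixation
#' events (exported indices or I-VT), trial segmentation, longest-fixation
#' selection, and the three quality metrics per trial. A trial is valid when
#' an eligible fixation (starting at or after trial onset) with at least one
#' valid sample is found.
#'
#' @param recording A [gaze_recording()].
#' @param display A [display_model()].
#' @param layout A [default_target_layout()] (or compatible data frame).
#' @param label_map Optional media-label to target-id map (see
#'   [segment_trials()]).
#' @param params An [ivt_params()].
#' @param accept_codes Validity codes accepted by [sample_is_valid()].
#' @param distance_cm Viewing distance override; when `NULL` the
#'   participant's mean recorded distance is used, falling back to
#'   `default_distance_cm` if the export has no distance data.
#' @param default_distance_cm Fallback viewing distance in cm.
#' @return An object of class `participant_quality`: list with
#'   `participant_id`, `distance_cm`, `trials` (one row per target trial:
#'   `target_id`, `media`, `onset_ms`, `valid`, `n_valid_samples`,
#'   `fix_start_ms`, `fix_duration_ms`, `accuracy_deg`, `sd_x_deg`,
#'   `sd_y_deg`, `rms_x_deg`, `rms_y_deg`, `n_bridged_pairs`, `outlier`),
#'   and summary fields filled by [summarize_participant()].
#' @export
participant_quality <- function(recording, display,
                                layout = default_target_layout(display),
                                label_map = NULL, params = ivt_params(),
                                accept_codes = 0L, distance_cm = NULL,
                                default_distance_cm = 60) {
  if (is.null(distance_cm)) {
    distance_cm <- tryCatch(participant_mean_distance(recording),
                            error = function(e) default_distance_cm)
  }
  fixations <- participant_fixations(recording, display, distance_cm,
                                     params, accept_codes)
  segs <- segment_trials(recording, label_map, targets = layout)
  trials <- segs[!is.na(segs$target_id), , drop = FALSE]
  s <- recording$samples

  one_trial <- function(i) {
    tg <- layout[layout$target_id == trials$target_id[i], , drop = FALSE]
    fx <- select_longest_valid_fixation(fixations, trials$onset_ms[i],
                                        trials$offset_ms[i])
    row <- data.frame(
      target_id = trials$target_id[i], media = trials$media[i],
      onset_ms = trials$onset_ms[i], valid = !is.null(fx),
      n_valid_samples = if (is.null(fx)) 0L else fx$n_valid,
      fix_start_ms = NA_real_, fix_duration_ms = NA_real_,
      accuracy_deg = NA_real_, sd_x_deg = NA_real_, sd_y_deg = NA_real_,
      rms_x_deg = NA_real_, rms_y_deg = NA_real_,
      n_bridged_pairs = NA_integer_, outlier = FALSE,
      stringsAsFactors = FALSE
    )
    if (!is.null(fx)) {
      row$fix_start_ms <- fx$start_ms
      row$fix_duration_ms <- fx$duration_ms
      row$accuracy_deg <- trial_accuracy(fx, c(tg$x_px, tg$y_px), display, distance_cm)
      sdp <- precision_sd(fx, s, display, distance_cm)
      rmp <- precision_rms(fx, s, display, distance_cm)
      row$sd_x_deg <- sdp[["sd_x"]]; row$sd_y_deg <- sdp[["sd_y"]]
      row$rms_x_deg <- rmp[["rms_x"]]; row$rms_y_deg <- rmp[["rms_y"]]
      row$n_bridged_pairs <- attr(rmp, "n_bridged_pairs") %||% NA_integer_
    }
    row
  }
  trial_rows <- if (nrow(trials)) {
    do.call(rbind, lapply(seq_len(nrow(trials)), one_trial))
  } else {
    one_trial(0)[0, ]
  }
  pq <- structure(
    list(participant_id = recording$participant_id,
         distance_cm = distance_cm, trials = trial_rows),
    class = "participant_quality"
  )
  summarize_participant(pq)
}

#' Summarise a participant's trial-quality table
#'
#' Counts valid trials and computes mean accuracy and precision over valid,
#' non-outlier trials. A participant with no valid trials is flagged as
#' having no valid fixations (discard candidate); means are then absent.
#'
#' @param pq A `participant_quality` object, or a trials data frame as
#'   produced by [participant_quality()] (then `participant_id` and
#'   `distance_cm` must be supplied).
#' @param participant_id,distance_cm Used when `pq` is a bare data frame.
#' @return A `participant_quality` object with `n_valid_trials`,
#'   `n_outlier_trials`, `no_valid_fixations`, and `mean_accuracy_deg`,
#'   `mean_sd_x_deg`, `mean_sd_y_deg`, `mean_rms_x_deg`, `mean_rms_y_deg`
#'   filled in (NA when no usable trials).
#' @export
summarize_participant <- function(pq, participant_id = NULL, distance_cm = NULL) {
  if (is.data.frame(pq)) {
    pq <- structure(list(participant_id = participant_id %||% "unknown",
                         distance_cm = distance_cm %||% NA_real_, trials = pq),
                    class = "participant_quality")
  }
  tr <- pq$trials
  use <- tr$valid & !tr$outlier
  pq$n_valid_trials <- sum(tr$valid)
  pq$n_outlier_trials <- sum(tr$outlier & tr$valid)
  pq$no_valid_fixations <- pq$n_valid_trials == 0L
  m <- function(col) if (any(use)) mean(tr[[col]][use], na.rm = TRUE) else NA_real_
  pq$mean_accuracy_deg <- m("accuracy_deg")
  pq$mean_sd_x_deg <- m("sd_x_deg")
  pq$mean_sd_y_deg <- m("sd_y_deg")
  pq$mean_rms_x_deg <- m("rms_x_deg")
  pq$mean_rms_y_deg <- m("rms_y_deg")
  pq
}

#' @export
print.participant_quality <- function(x, ...) {
  cat(sprintf("<participant_quality> %s: %d/%d valid trials", x$participant_id,
              x$n_valid_trials, nrow(x$trials)))
  if (x$no_valid_fixations) {
    cat(" (no valid fixations)\n")
  } else {
    cat(sprintf(", mean accuracy %.2f deg (SD %.2f, %.2f; RMS %.2f, %.2f)\n",
                x$mean_accuracy_deg, x$mean_sd_x_deg, x$mean_sd_y_deg,
                x$mean_rms_x_deg, x$mean_rms_y_deg))
  }
  invisible(x)
}
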