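#' Canonical gaze-export column schema
#'
#' Maps the logical sample fields used throughout the package to the column
#' names found in a tab-separated gaze export. The canonical names double as
#' the default, so exports written by [write_gaze_export()] round-trip with
#' no mapping. To read a vendor dialect, supply the vendor's column names,
#' e.g. `default_schema(t_ms = "RecordingTimestamp", media = "MediaName")`.
#'
#' Logical fields: `t_ms` (timestamp), `media` (on-screen stimulus label),
#' `fix_idx` (vendor fixation index, optional), `x_px`, `y_px` (two-eye
#' average gaze in pixels), `dist_l_cm`, `dist_r_cm` (per-eye distance to
#' screen), `val_l`, `val_r` (per-eye validity codes), `participant`
#' (optional; may instead be given when reading).
#'
#' @param ... Named overrides `logical_field = "column name"`.
#' @return Named character vector mapping logical fields to column names.
#' @export
default_schema <- function(...) {
  schema <- c(
    participant = "participant", t_ms = "t_ms", media = "media",
    fix_idx = "fix_idx", x_px = "x_px", y_px = "y_px",
    dist_l_cm = "dist_l_cm", dist_r_cm = "dist_r_cm",
    val_l = "val_l", val_r = "val_r"
  )
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(schema))
    if (length(unknown)) {
      stop("unknown schema field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    schema[names(dots)] <- dots
  }
  schema
}

#' Gaze recording container
#'
#' @param participant_id Participant identifier.
#' @param samples Data frame of samples in canonical column order
#'   (`t_ms`, `media`, `fix_idx`, `x_px`, `y_px`, `dist_l_cm`, `dist_r_cm`,
#'   `val_l`, `val_r`), ordered by timestamp.
#' @param nominal_rate_hz Nominal sampling rate in Hz (default 300).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, samples, nominal_rate_hz = 300) {
  if (!is.numeric(nominal_rate_hz) || nominal_rate_hz <= 0) {
    stop("nominal_rate_hz must be positive", call. = FALSE)
  }
  needed <- c("t_ms", "media", "fix_idx", "x_px", "y_px",
              "dist_l_cm", "dist_r_cm", "val_l", "val_r")
  missing <- setdiff(needed, names(samples))
  if (length(missing)) {
    stop("samples lack column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(samples$t_ms)) {
    samples <- samples[order(samples$t_ms), , drop = FALSE]
  }
  rownames(samples) <- NULL
  structure(
    list(participant_id = as.character(participant_id),
         samples = samples[, needed, drop = FALSE],
         nominal_rate_hz = nominal_rate_hz),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  span <- if (n) diff(range(x$samples$t_ms)) else 0
  cat(sprintf("<gaze_recording> participant %s: %d samples, %.0f ms @ %g Hz\n",
              x$participant_id, n, span, x$nominal_rate_hz))
  invisible(x)
}

parse_num <- function(x, na_values, na_coord_values = numeric()) {
  x <- as.character(x)
  x[trimws(x) %in% na_values] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable numeric value '%s' at data row %d", x[bad[1]], bad[1]),
         call. = FALSE)
  }
  if (length(na_coord_values)) out[out %in% na_coord_values] <- NA_real_
  out
}

#' Read a tab-separated gaze export
#'
#' Parses one participant's gaze export into a [gaze_recording()]. Missing
#' numeric cells (empty, or listed in `na_values` / `na_coord_values`)
#' become `NA`, never zeros. Rows are ordered by timestamp and exact
#' duplicate timestamps are dropped (first occurrence kept).
#'
#' @param path Path to a tab-separated UTF-8 file with a header row.
#' @param schema Column-name mapping from [default_schema()].
#' @param participant_id Used if the export has no participant column.
#' @param nominal_rate_hz Nominal sampling rate in Hz.
#' @param na_values Strings treated as missing in any numeric column.
#' @param na_coord_values Numeric sentinel values (e.g. -1) treated as
#'   missing gaze coordinates.
#' @param timestamp_unit `"ms"` (default) or `"us"`; microsecond stamps are
#'   converted to ms.
#' @return A [gaze_recording()].
#' @export
read_gaze_export <- function(path, schema = default_schema(),
                             participant_id = NULL, nominal_rate_hz = 300,
                             na_values = c("", "NA", "nan"),
                             na_coord_values = -1,
                             timestamp_unit = c("ms", "us")) {
  timestamp_unit <- match.arg(timestamp_unit)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", comment.char = "")
  required <- setdiff(names(default_schema()), c("participant", "fix_idx"))
  for (field in required) {
    if (!schema[[field]] %in% names(raw)) {
      stop(sprintf("schema error: mapped column '%s' (field %s) not found in %s",
                   schema[[field]], field, path), call. = FALSE)
    }
  }
  n <- nrow(raw)
  col <- function(field) if (schema[[field]] %in% names(raw)) raw[[schema[[field]]]] else NULL
  t_raw <- col("t_ms")
  t_ms <- tryCatch(parse_num(t_raw, na_values),
                   error = function(e) stop(conditionMessage(e), " (timestamp column)",
                                            call. = FALSE))
  if (anyNA(t_ms)) {
    stop(sprintf("unparseable timestamp at data row %d", which(is.na(t_ms))[1]),
         call. = FALSE)
  }
  if (timestamp_unit == "us") t_ms <- t_ms / 1000
  fix_col <- col("fix_idx")
  samples <- data.frame(
    t_ms = t_ms,
    media = if (n) as.character(col("media")) else character(),
    fix_idx = if (!is.null(fix_col)) as.integer(parse_num(fix_col, na_values))
              else rep(NA_integer_, n),
    x_px = parse_num(col("x_px"), na_values, na_coord_values),
    y_px = parse_num(col("y_px"), na_values, na_coord_values),
    dist_l_cm = parse_num(col("dist_l_cm"), na_values),
    dist_r_cm = parse_num(col("dist_r_cm"), na_values),
    val_l = as.integer(parse_num(col("val_l"), na_values)),
    val_r = as.integer(parse_num(col("val_r"), na_values)),
    stringsAsFactors = FALSE
  )
  # stable order, then drop exact duplicate timestamps keeping the first
  samples <- samples[order(samples$t_ms), , drop = FALSE]
  samples <- samples[!duplicated(samples$t_ms), , drop = FALSE]
  pid <- if (!is.null(col("participant")) && n > 0) col("participant")[1]
         else participant_id %||% sub("\\.[^.]*$", "", basename(path))
  gaze_recording(pid, samples, nominal_rate_hz)
}

#' Write a recording as a canonical tab-separated export
#'
#' Columns are written in the fixed canonical order with a participant
#' column first; missing values become empty cells. Numeric values are
#' written with 17 significant digits so finite values round-trip
#' bit-identically through [read_gaze_export()].
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_export <- function(recording, path) {
  s <- recording$samples
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(
    participant = rep(recording$participant_id, nrow(s)),
    t_ms = fmt(s$t_ms), media = s$media,
    fix_idx = ifelse(is.na(s$fix_idx), "", as.character(s$fix_idx)),
    x_px = fmt(s$x_px), y_px = fmt(s$y_px),
    dist_l_cm = fmt(s$dist_l_cm), dist_r_cm = fmt(s$dist_r_cm),
    val_l = ifelse(is.na(s$val_l), "", as.character(s$val_l)),
    val_r = ifelse(is.na(s$val_r), "", as.character(s$val_r)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Per-sample validity under the inclusion rule
#'
#' A sample is valid iff at least one eye's validity code is accepted
#' (the 0-4 vendor convention, 0 = eye found with certainty), gaze
#' coordinates are present, and the gaze point lies on-screen
#' (`0 <= x < resolution_x`, `0 <= y < resolution_y`). Off-screen samples
#' are invalid regardless of their validity codes.
#'
#' @param samples Canonical samples data frame (or a [gaze_recording()]).
#' @param display A [display_model()].
#' @param accept_codes Integer validity codes counted as a valid reading;
#'   default `0` (certain); use `c(0, 1)` for a permissive policy.
#' @return Logical vector, one element per sample.
#' @export
sample_is_valid <- function(samples, display, accept_codes = 0L) {
  if (inherits(samples, "gaze_recording")) samples <- samples$samples
  stopifnot_display(display)
  eye_ok <- (samples$val_l %in% accept_codes) | (samples$val_r %in% accept_codes)
  present <- !is.na(samples$x_px) & !is.na(samples$y_px)
  on_screen <- present &
    samples$x_px >= 0 & samples$x_px < display$resolution_x &
    samples$y_px >= 0 & samples$y_px < display$resolution_y
  eye_ok & on_screen
}

#' Segment a recording into trials by stimulus label
#'
#' One segment per contiguous run of a media label. Labels are mapped to
#' target ids via `label_map`; unmapped labels are kept with `target_id`
#' `NA` (the "unassigned" bin) rather than silently dropped.
#'
#' @param recording A [gaze_recording()].
#' @param label_map Named character vector `c(media_label = target_id)`, or
#'   `NULL` to use media labels as target ids directly.
#' @param targets Optional [default_target_layout()]; when given with
#'   `label_map = NULL`, only media labels matching its target ids are
#'   assigned.
#' @return Data frame with one row per segment: `segment_id`, `media`,
#'   `target_id`, `onset_ms`, `offset_ms`, `first_idx`, `last_idx`,
#'   `n_samples`. `offset_ms` is the onset of the following segment (or the
#'   last timestamp plus one nominal sample period for the final segment).
#' @export
segment_trials <- function(recording, label_map = NULL, targets = NULL) {
  s <- recording$samples
  if (!nrow(s)) {
    return(data.frame(segment_id = integer(), media = character(),
                      target_id = character(), onset_ms = numeric(),
                      offset_ms = numeric(), first_idx = integer(),
                      last_idx = integer(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(s$media)
  last <- cumsum(r$lengths)
  first <- c(1L, utils::head(last, -1L) + 1L)
  dt <- 1000 / recording$nominal_rate_hz
  onset <- s$t_ms[first]
  offset <- c(onset[-1], s$t_ms[last[length(last)]] + dt)
  if (is.null(label_map)) {
    target_id <- r$values
    if (!is.null(targets)) target_id[!target_id %in% targets$target_id] <- NA_character_
  } else {
    target_id <- unname(label_map[r$values])
  }
  if (all(is.na(target_id))) {
    warning("no media labels matched the label map; all segments unassigned",
            call. = FALSE)
  }
  data.frame(
    segment_id = seq_along(r$values), media = r$values, target_id = target_id,
    onset_ms = onset, offset_ms = offset,
    first_idx = first, last_idx = last, n_samples = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Mean viewing distance over a recording
#'
#' Mean over samples of the per-sample mean of whichever eye distances are
#' present; samples with neither distance contribute nothing.
#'
#' @param recording A [gaze_recording()] (or canonical samples data frame).
#' @return Distance in cm.
#' @export
participant_mean_distance <- function(recording) {
  s <- if (inherits(recording, "gaze_recording")) recording$samples else recording
  per_sample <- rowMeans(cbind(s$dist_l_cm, s$dist_r_cm), na.rm = TRUE)
  per_sample <- per_sample[is.finite(per_sample)]
  if (!length(per_sample)) {
    stop("missing-distance: no eye-to-screen distance data in recording; ",
         "supply distance_cm from the configured default", call. = FALSE)
  }
  mean(per_sample)
}
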