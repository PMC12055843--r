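#' Angular gaze velocity between consecutive samples
#'
#' Converts the pixel displacement between two gaze samples into visual
#' angle and divides by the elapsed time. The visual angle subtended by a
#' displacement of `d` millimetres on the screen at viewing distance `D` is
#' `2 * atan(d / (2 * D))` degrees.
#'
#' Vectorised: `x`, `y`, `t_ms` may be vectors, in which case the velocity
#' of each consecutive segment is returned (length `n - 1`).
#'
#' @param x,y Gaze coordinates in pixels.
#' @param t_ms Timestamps in milliseconds, strictly increasing.
#' @param geometry A [screen_geometry()].
#' @return Angular speed(s) in degrees per second.
#' @export
#' @examples
#' g <- screen_geometry()
#' sample_velocity(c(0, 100), c(0, 0), c(0, 35.17), g)  # ~81.3 deg/s
sample_velocity <- function(x, y, t_ms, geometry) {
  dt <- diff(t_ms)
  if (any(dt <= 0)) stop("data error: non-increasing timestamps", call. = FALSE)
  d_px <- sqrt(diff(x)^2 + diff(y)^2)
  d_mm <- d_px * geometry$pixel_pitch_mm
  angle_deg <- 2 * atan(d_mm / (2 * geometry$viewing_distance_mm)) * 180 / pi
  angle_deg / (dt / 1000)
}

new_event_stream <- function(fixations, saccades, discarded_short_runs = 0L,
                             saccade_samples = 0L, aoi_removed = 0L) {
  structure(list(fixations = fixations, saccades = saccades,
                 discarded = list(short_runs = as.integer(discarded_short_runs),
                                  saccade_samples = as.integer(saccade_samples)),
                 aoi_removed = as.integer(aoi_removed)),
            class = "event_stream")
}

empty_fixations <- function() {
  tibble::tibble(t_start_ms = numeric(), t_end_ms = numeric(),
                 x_px = numeric(), y_px = numeric(),
                 n_samples = integer(), inside_aoi = logical())
}

empty_saccades <- function() {
  tibble::tibble(s_start_ms = numeric(), s_end_ms = numeric(),
                 x_start_px = numeric(), y_start_px = numeric(),
                 x_end_px = numeric(), y_end_px = numeric())
}

#' @export
print.event_stream <- function(x, ...) {
  cat("<event_stream> ", nrow(x$fixations), " fixation(s), ",
      nrow(x$saccades), " saccade(s); discarded: ",
      x$discarded$short_runs, " short run(s), ",
      x$discarded$saccade_samples, " saccade sample(s); ",
      x$aoi_removed, " removed by AOI\n", sep = "")
  invisible(x)
}

# Rebuild the saccade table as the inter-fixation gaps of `fx`.
saccades_between <- function(fx) {
  n <- nrow(fx)
  if (n < 2L) return(empty_saccades())
  tibble::tibble(
    s_start_ms = fx$t_end_ms[-n], s_end_ms = fx$t_start_ms[-1L],
    x_start_px = fx$x_px[-n], y_start_px = fx$y_px[-n],
    x_end_px = fx$x_px[-1L], y_end_px = fx$y_px[-1L]
  )
}

#' Classify a gaze-sample stream into fixations and saccades
#'
#' Velocity-threshold (I-VT) classification: each inter-sample segment is
#' labelled saccadic when its angular velocity exceeds the configured
#' threshold. Maximal runs of samples joined only by sub-threshold segments
#' form fixation candidates; a candidate becomes a fixation when its span
#' (last minus first sample time) reaches the minimum fixation duration,
#' otherwise it is discarded and counted. All samples within a fixation are
#' snapped to the first sample's coordinate. Saccade-labelled samples are
#' transitional and excluded; each saccade event is reconstructed as the
#' gap between the end of one fixation and the start of the next, with the
#' two snapped coordinates as endpoints.
#'
#' @param samples Tibble with `t_ms`, `x_px`, `y_px` for one trial,
#'   timestamps strictly increasing.
#' @param config A [pipeline_config()].
#' @return An `event_stream`: `$fixations` (with `inside_aoi` flag from the
#'   configured AOI), `$saccades`, and `$discarded` counts. Fewer than two
#'   samples yield an empty stream, not an error.
#' @export
classify_events <- function(samples, config = pipeline_config()) {
  geometry <- config$geometry
  t <- samples$t_ms; x <- samples$x_px; y <- samples$y_px
  n <- length(t)
  if (n == 0L) return(new_event_stream(empty_fixations(), empty_saccades()))
  if (n == 1L)
    return(new_event_stream(empty_fixations(), empty_saccades(),
                            discarded_short_runs = 1L))
  if (any(diff(t) <= 0))
    stop("data error: timestamps must be strictly increasing", call. = FALSE)

  v <- sample_velocity(x, y, t, geometry)
  saccadic <- v > config$velocity_threshold_deg_s

  # Candidate runs: blocks of samples whose internal segments are all
  # sub-threshold. A saccadic segment cuts between sample i and i+1.
  run_id <- cumsum(c(0L, as.integer(saccadic)))
  first <- !duplicated(run_id)
  last <- !duplicated(run_id, fromLast = TRUE)
  i0 <- which(first); i1 <- which(last)
  span <- t[i1] - t[i0]
  keep <- span >= config$min_fixation_ms

  fx <- tibble::tibble(
    t_start_ms = t[i0][keep], t_end_ms = t[i1][keep],
    x_px = x[i0][keep], y_px = y[i0][keep],
    n_samples = (i1 - i0 + 1L)[keep],
    inside_aoi = in_aoi(x[i0][keep], y[i0][keep], config$aoi)
  )
  # Saccade-labelled samples: none exist as distinct samples in this
  # representation (segments, not samples, carry the label); what is
  # excluded are the samples of sub-threshold runs too short to be
  # fixations.
  new_event_stream(fx, saccades_between(fx),
                   discarded_short_runs = sum(!keep),
                   saccade_samples = sum((i1 - i0 + 1L)[!keep]))
}

#' Restrict an event stream to the area of interest
#'
#' Removes fixations whose snapped coordinate falls outside the half-open
#' AOI box and rebuilds the saccades between the surviving consecutive
#' fixations, so that saccade endpoints and times always refer to retained
#' fixations. The number of removed fixations is recorded in
#' `$aoi_removed`.
#'
#' @param stream An `event_stream` from [classify_events()].
#' @param aoi An [aoi_spec()].
#' @return A filtered `event_stream`.
#' @export
apply_aoi <- function(stream, aoi) {
  fx <- stream$fixations
  inside <- in_aoi(fx$x_px, fx$y_px, aoi)
  fx <- fx[inside, ]
  fx$inside_aoi <- rep(TRUE, nrow(fx))
  out <- new_event_stream(fx, saccades_between(fx),
                          discarded_short_runs = stream$discarded$short_runs,
                          saccade_samples = stream$discarded$saccade_samples,
                          aoi_removed = stream$aoi_removed + sum(!inside))
  out
}

#' Preprocess all trials of a gaze recording
#'
#' Runs [classify_events()] and [apply_aoi()] on every trial of a raw
#' gaze-sample table and returns the events in the long CSV layout used by
#' [write_events_csv()]. Saccade rows carry their start coordinate in
#' `x_px`/`y_px` and end coordinate in `x_end_px`/`y_end_px`.
#'
#' @param samples Gaze-sample tibble from [read_gaze_csv()] (multiple
#'   trials).
#' @param config A [pipeline_config()].
#' @param apply_aoi_filter Remove fixations outside the AOI (default TRUE).
#' @return Tibble of events with a `trial_id` column.
#' @export
preprocess_trials <- function(samples, config = pipeline_config(),
                              apply_aoi_filter = TRUE) {
  ids <- unique(samples$trial_id)
  rows <- lapply(ids, function(id) {
    s <- samples[samples$trial_id == id, ]
    st <- classify_events(s, config)
    if (apply_aoi_filter) st <- apply_aoi(st, config$aoi)
    events_to_table(st, id)
  })
  dplyr::bind_rows(rows)
}

#' Flatten an event stream to the long event-table layout
#'
#' @param stream An `event_stream`.
#' @param trial_id Trial identifier attached to every row.
#' @return Tibble with one row per event.
#' @export
events_to_table <- function(stream, trial_id) {
  fx <- stream$fixations; sc <- stream$saccades
  f <- tibble::tibble(trial_id = rep(trial_id, nrow(fx)), kind = rep("fixation", nrow(fx)),
                      t_start_ms = fx$t_start_ms, t_end_ms = fx$t_end_ms,
                      x_px = fx$x_px, y_px = fx$y_px,
                      x_end_px = rep(NA_real_, nrow(fx)), y_end_px = rep(NA_real_, nrow(fx)),
                      inside_aoi = fx$inside_aoi)
  s <- tibble::tibble(trial_id = rep(trial_id, nrow(sc)), kind = rep("saccade", nrow(sc)),
                      t_start_ms = sc$s_start_ms, t_end_ms = sc$s_end_ms,
                      x_px = sc$x_start_px, y_px = sc$y_start_px,
                      x_end_px = sc$x_end_px, y_end_px = sc$y_end_px,
                      inside_aoi = rep(NA, nrow(sc)))
  out <- dplyr::bind_rows(f, s)
  out[order(out$t_start_ms, match(out$kind, c("fixation", "saccade"))), ]
}

#' Rebuild an event stream from the long event-table layout
#'
#' Inverse of [events_to_table()] for a single trial (discard counts are
#' not stored in the table and come back as zero).
#'
#' @param events Event tibble for one trial.
#' @return An `event_stream`.
#' @export
table_to_events <- function(events) {
  f <- events[events$kind == "fixation", ]
  f <- f[order(f$t_start_ms), ]
  fx <- tibble::tibble(t_start_ms = f$t_start_ms, t_end_ms = f$t_end_ms,
                       x_px = f$x_px, y_px = f$y_px,
                       n_samples = rep(NA_integer_, nrow(f)),
                       inside_aoi = f$inside_aoi)
  new_event_stream(fx, saccades_between(fx))
}
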