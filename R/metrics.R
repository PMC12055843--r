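#' Six per-trial eye-tracking metrics
#'
#' From an AOI-filtered event stream, computes:
#' \describe{
#'   \item{FC}{fixation count;}
#'   \item{FD}{total fixation duration, the sum of `t_end - t_start` over
#'     fixations, in ms;}
#'   \item{SC}{saccade count;}
#'   \item{SD}{total saccade duration, the sum of `s_end - s_start` over
#'     inter-fixation gaps, in ms;}
#'   \item{SST}{saccade scanpath total, the summed Euclidean pixel distance
#'     between the snapped coordinates flanking each saccade;}
#'   \item{SAT}{saccade amplitude total, the summed direction angle
#'     `atan(|dy| / |dx|)` of each saccade in degrees — the acute angle of
#'     the displacement relative to horizontal, so a horizontal saccade
#'     contributes 0 and a vertical one 90.}
#' }
#' SAT as defined is a summed direction angle, not a visual-angle
#' amplitude; the conventional amplitude (visual angle subtended by the
#' displacement) is returned alongside as `SAT_visual_deg` and is never
#' substituted for SAT.
#'
#' @param stream An `event_stream`, normally after [apply_aoi()].
#' @param geometry A [screen_geometry()] used only for `SAT_visual_deg`.
#' @return A one-row tibble `FC, FD, SC, SD, SST, SAT, SAT_visual_deg`.
#'   An empty stream gives all zeros.
#' @export
#' @examples
#' st <- classify_events(
#'   tibble::tibble(t_ms = c(0, 50, 100, 140, 190, 240),
#'                  x_px = c(500, 500, 500, 900, 900, 900),
#'                  y_px = c(500, 500, 500, 700, 700, 700)))
#' compute_trial_metrics(st)
compute_trial_metrics <- function(stream, geometry = screen_geometry()) {
  fx <- stream$fixations; sc <- stream$saccades
  dx <- abs(sc$x_end_px - sc$x_start_px)
  dy <- abs(sc$y_end_px - sc$y_start_px)
  step_px <- sqrt(dx^2 + dy^2)
  amp_deg <- 2 * atan(step_px * geometry$pixel_pitch_mm /
                        (2 * geometry$viewing_distance_mm)) * 180 / pi
  tibble::tibble(
    FC = nrow(fx),
    FD = sum(fx$t_end_ms - fx$t_start_ms),
    SC = nrow(sc),
    SD = sum(sc$s_end_ms - sc$s_start_ms),
    SST = sum(step_px),
    SAT = sum(atan2(dy, dx)) * 180 / pi,
    SAT_visual_deg = sum(amp_deg)
  )
}

#' Per-trial metrics for a whole recording
#'
#' Maps [compute_trial_metrics()] over the trials of a long event table.
#'
#' @param events Event tibble from [preprocess_trials()] or
#'   [read_events_csv()].
#' @param geometry A [screen_geometry()].
#' @return Tibble with one row per trial: `trial_id` plus the metric
#'   columns.
#' @export
compute_metrics <- function(events, geometry = screen_geometry()) {
  ids <- unique(events$trial_id)
  rows <- lapply(ids, function(id) {
    m <- compute_trial_metrics(table_to_events(events[events$trial_id == id, ]),
                               geometry)
    dplyr::bind_cols(tibble::tibble(trial_id = id), m)
  })
  dplyr::bind_rows(rows)
}

#' Aggregate trial metrics to participant summaries
#'
#' Computes the unweighted mean of each metric over trials within
#' participant x response type. Three response types are emitted per
#' participant: `correct`, `incorrect`, and `all`; a participant with no
#' trials of a type simply has no row for it (absent, not zero). Group
#' statistics downstream operate on these participant-level means.
#'
#' @param trial_metrics Tibble from [compute_metrics()].
#' @param trials Trial table from [read_trial_table()].
#' @return Tibble: `participant_id`, `group`, `response_type`, `n_trials`,
#'   and the mean of each metric.
#' @export
aggregate_participants <- function(trial_metrics, trials) {
  missing_ids <- setdiff(trial_metrics$trial_id, trials$trial_id)
  if (length(missing_ids))
    stop("data error: no trial-table entry for trial_id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  metric_cols <- setdiff(names(trial_metrics), "trial_id")
  joined <- dplyr::inner_join(trial_metrics, trials, by = "trial_id")
  joined$response_type <- ifelse(joined$response_correct == 1L,
                                 "correct", "incorrect")

  summarise_cell <- function(df) {
    dplyr::summarise(df,
                     n_trials = dplyr::n(),
                     dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
  }
  by_type <- summarise_cell(
    dplyr::group_by(joined, .data$participant_id, .data$group,
                    .data$response_type))
  overall <- summarise_cell(
    dplyr::group_by(joined, .data$participant_id, .data$group))
  overall <- dplyr::mutate(overall, response_type = "all",
                           .after = "group")
  out <- dplyr::bind_rows(by_type, overall)
  dplyr::arrange(out, .data$participant_id, .data$response_type)
}
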