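#' Screen geometry of the recording setup
#'
#' Describes the display and viewing conditions needed to convert pixel
#' displacements into visual angle. The default profile is a 23.8-inch
#' full-HD monitor (1,920 x 1,080, pixel pitch 0.2745 mm) viewed from
#' 550 mm, sampled at a nominal 28.43 Hz.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param pixel_pitch_mm Physical size of one pixel in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @param sample_rate_hz Nominal gaze sampling frequency in Hz.
#' @return An object of class `screen_geometry`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' geom$sample_rate_hz
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            pixel_pitch_mm = 0.2745,
                            viewing_distance_mm = 550,
                            sample_rate_hz = 28.43) {
  g <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            pixel_pitch_mm = pixel_pitch_mm,
            viewing_distance_mm = viewing_distance_mm,
            sample_rate_hz = sample_rate_hz)
  for (k in names(g)) {
    if (!is.numeric(g[[k]]) || length(g[[k]]) != 1L || !is.finite(g[[k]]) ||
        g[[k]] <= 0) {
      stop("screen_geometry: `", k, "` must be a single positive number",
           call. = FALSE)
    }
  }
  structure(g, class = "screen_geometry")
}

#' Rectangular area of interest (AOI)
#'
#' Pixel bounds of the stimulus region, half-open on the right/bottom:
#' a point (x, y) is inside iff `x_min <= x < x_max` and
#' `y_min <= y < y_max`. The default centres a 1,483 x 707 px region in a
#' 1,920 x 1,080 display, flooring the half margins, giving
#' x in \[218, 1701) and y in \[186, 893).
#'
#' @param x_min,y_min,x_max,y_max Pixel bounds.
#' @param geometry A [screen_geometry()] used to validate the bounds.
#' @return An object of class `aoi_spec`.
#' @export
aoi_spec <- function(x_min = NULL, y_min = NULL, x_max = NULL, y_max = NULL,
                     geometry = screen_geometry()) {
  if (is.null(x_min)) {
    a <- centered_aoi(1483L, 707L, geometry)
    x_min <- a$x_min; y_min <- a$y_min; x_max <- a$x_max; y_max <- a$y_max
  }
  a <- list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (!(a$x_min >= 0 && a$x_min < a$x_max && a$x_max <= geometry$width_px))
    stop("aoi_spec: need 0 <= x_min < x_max <= width_px", call. = FALSE)
  if (!(a$y_min >= 0 && a$y_min < a$y_max && a$y_max <= geometry$height_px))
    stop("aoi_spec: need 0 <= y_min < y_max <= height_px", call. = FALSE)
  structure(a, class = "aoi_spec")
}

#' Centre an AOI of given size on the screen
#'
#' Margins are halved and floored to integer pixels.
#'
#' @param width_px,height_px AOI dimensions in pixels.
#' @param geometry A [screen_geometry()].
#' @return An `aoi_spec`.
#' @export
centered_aoi <- function(width_px, height_px, geometry = screen_geometry()) {
  x0 <- floor((geometry$width_px - width_px) / 2)
  y0 <- floor((geometry$height_px - height_px) / 2)
  aoi_spec(x0, y0, x0 + width_px, y0 + height_px, geometry = geometry)
}

#' Is a point inside the AOI?
#'
#' Vectorised over coordinates; half-open bounds.
#'
#' @param x,y Pixel coordinates.
#' @param aoi An [aoi_spec()].
#' @return Logical vector.
#' @export
in_aoi <- function(x, y, aoi) {
  x >= aoi$x_min & x < aoi$x_max & y >= aoi$y_min & y < aoi$y_max
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis: screen geometry, AOI,
#' the minimum fixation duration (ms), the saccade velocity threshold
#' (degrees of visual angle per second), the spatial grid dimensions, the
#' entropy logarithm base, the significance level, and a seed for any
#' stochastic step.
#'
#' @param geometry A [screen_geometry()].
#' @param aoi An [aoi_spec()].
#' @param min_fixation_ms Minimum duration for a valid fixation (default 70).
#' @param velocity_threshold_deg_s Saccade velocity cutoff (default 30).
#' @param grid_rows,grid_cols Spatial grid dimensions (default 10 x 10).
#' @param entropy_log_base Base of the entropy logarithm (default 2, bits).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = screen_geometry(),
                            aoi = aoi_spec(geometry = geometry),
                            min_fixation_ms = 70,
                            velocity_threshold_deg_s = 30,
                            grid_rows = 10L, grid_cols = 10L,
                            entropy_log_base = 2,
                            alpha = 0.05,
                            seed = 1L) {
  stopifnot(inherits(geometry, "screen_geometry"), inherits(aoi, "aoi_spec"))
  if (min_fixation_ms <= 0)
    stop("config error: `min_fixation_ms` must be > 0", call. = FALSE)
  if (velocity_threshold_deg_s <= 0)
    stop("config error: `velocity_threshold_deg_s` must be > 0", call. = FALSE)
  if (grid_rows < 1 || grid_cols < 1)
    stop("config error: grid dimensions must be >= 1", call. = FALSE)
  if (entropy_log_base <= 1)
    stop("config error: `entropy_log_base` must be > 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("config error: `alpha` must be in (0, 1)", call. = FALSE)
  structure(list(geometry = geometry, aoi = aoi,
                 min_fixation_ms = min_fixation_ms,
                 velocity_threshold_deg_s = velocity_threshold_deg_s,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 entropy_log_base = entropy_log_base,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a flat YAML file
#'
#' Keys absent from the file fall back to the default profile (70 ms
#' minimum fixation, 30 deg/s velocity threshold, 10 x 10 grid, alpha 0.05,
#' centred 1,483 x 707 AOI on a 1,920 x 1,080 display). An empty file
#' yields the full default profile. Out-of-range values raise a config
#' error naming the offending key.
#'
#' @param path Path to a flat key-value YAML file (may be empty).
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config error: expected flat key-value file", call. = FALSE)

  geom_keys <- c("width_px", "height_px", "pixel_pitch_mm",
                 "viewing_distance_mm", "sample_rate_hz")
  gdef <- screen_geometry()
  gargs <- lapply(geom_keys, function(k) if (!is.null(raw[[k]])) raw[[k]] else gdef[[k]])
  names(gargs) <- geom_keys
  geometry <- tryCatch(do.call(screen_geometry, gargs),
                       error = function(e) stop("config error: ", conditionMessage(e),
                                                call. = FALSE))

  aoi_keys <- c("aoi_x_min", "aoi_y_min", "aoi_x_max", "aoi_y_max")
  if (any(aoi_keys %in% names(raw))) {
    if (!all(aoi_keys %in% names(raw)))
      stop("config error: AOI overrides require all of ",
           paste(aoi_keys, collapse = ", "), call. = FALSE)
    aoi <- aoi_spec(raw$aoi_x_min, raw$aoi_y_min, raw$aoi_x_max, raw$aoi_y_max,
                    geometry = geometry)
  } else {
    aoi <- aoi_spec(geometry = geometry)
  }

  cfg_keys <- c("min_fixation_ms", "velocity_threshold_deg_s", "grid_rows",
                "grid_cols", "entropy_log_base", "alpha", "seed")
  cargs <- raw[intersect(cfg_keys, names(raw))]
  known <- c(geom_keys, aoi_keys, cfg_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, c(list(geometry = geometry, aoi = aoi), cargs))
}

#' Read a raw gaze-sample CSV
#'
#' Expects the columns `trial_id,t_ms,x_px,y_px`; timestamps must be
#' strictly increasing within each trial. Off-screen coordinates are kept
#' and flagged in an `off_screen` column rather than dropped.
#'
#' @param path Path to the CSV file.
#' @param geometry A [screen_geometry()] used for the off-screen flag.
#' @return A tibble with columns `trial_id`, `t_ms`, `x_px`, `y_px`,
#'   `off_screen`, ordered as on file.
#' @export
read_gaze_csv <- function(path, geometry = screen_geometry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "t_ms", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: gaze CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  df$trial_id <- as.character(df$trial_id)
  if (nrow(df)) {
    bad <- unlist(lapply(split(df$t_ms, df$trial_id),
                         function(t) any(diff(t) <= 0)))
    if (any(bad))
      stop("data error: non-monotone timestamps in trial(s): ",
           paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  df$off_screen <- !(df$x_px >= 0 & df$x_px < geometry$width_px &
                       df$y_px >= 0 & df$y_px < geometry$height_px)
  tibble::as_tibble(df)
}

#' Write a gaze-sample CSV
#'
#' Inverse of [read_gaze_csv()]; round-trips are lossless.
#'
#' @param samples Tibble with `trial_id`, `t_ms`, `x_px`, `y_px`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(samples, path) {
  utils::write.csv(samples[c("trial_id", "t_ms", "x_px", "y_px")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table CSV
#'
#' Expects `trial_id,participant_id,group,item,response_correct` and an
#' optional free-text `error_type` column. Groups must be `NPH` or `HE`;
#' `response_correct` must be 0/1; trial ids must be unique.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated trial records.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("trial_id", "participant_id", "group", "item", "response_correct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: trial table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"error_type" %in% names(df))
    df$error_type <- rep(NA_character_, nrow(df))
  df <- df[c(need, "error_type")]
  if (nrow(df)) {
    bad_group <- setdiff(unique(df$group), c("NPH", "HE"))
    if (length(bad_group))
      stop("data error: unknown group label(s): ",
           paste(bad_group, collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$trial_id))
      stop("data error: duplicate trial_id(s): ",
           paste(unique(df$trial_id[duplicated(df$trial_id)]), collapse = ", "),
           call. = FALSE)
    if (!all(df$response_correct %in% c("0", "1")))
      stop("data error: response_correct must be 0 or 1", call. = FALSE)
  }
  df$response_correct <- as.integer(df$response_correct)
  tibble::as_tibble(df)
}

#' Write a trial table CSV
#'
#' @param trials Tibble as returned by [read_trial_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  out <- trials[c("trial_id", "participant_id", "group", "item",
                  "response_correct", "error_type")]
  if (all(is.na(out$error_type))) out$error_type <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write classified events to CSV
#'
#' One row per fixation or saccade, long format:
#' `trial_id,kind,t_start_ms,t_end_ms,x_px,y_px,x_end_px,y_end_px,inside_aoi`
#' (`x_end_px`/`y_end_px` are blank for fixations, which have a single
#' snapped coordinate).
#'
#' @param events Tibble of events as produced by [preprocess_trials()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a classified-events CSV written by [write_events_csv()]
#'
#' @param path Path to the events CSV.
#' @return Tibble of events.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "kind", "t_start_ms", "t_end_ms", "x_px", "y_px",
            "x_end_px", "y_end_px", "inside_aoi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: events CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$trial_id <- as.character(df$trial_id)
  df$inside_aoi <- as.logical(df$inside_aoi)
  tibble::as_tibble(df)
}
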