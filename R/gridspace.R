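#' Assign AOI fixations to grid cells
#'
#' Partitions the AOI rectangle into `rows x cols` equal half-open cells
#' and maps each inside fixation to exactly one cell. Fixations exactly on
#' the maximum edge (possible only when the AOI filter is bypassed) map to
#' the last cell.
#'
#' @param fixations Tibble with `x_px`, `y_px` (AOI-filtered fixations, in
#'   temporal order).
#' @param aoi An [aoi_spec()].
#' @param rows,cols Grid dimensions (default 10 x 10).
#' @return A `grid_assignment`: per-fixation 0-based `row`/`col` indices
#'   and a linear `cell` id (row-major), plus counts of inside and total
#'   fixations.
#' @export
assign_grid <- function(fixations, aoi, rows = 10L, cols = 10L) {
  stopifnot(rows >= 1L, cols >= 1L)
  inside <- in_aoi(fixations$x_px, fixations$y_px, aoi)
  fx <- fixations[inside, ]
  cell_w <- (aoi$x_max - aoi$x_min) / cols
  cell_h <- (aoi$y_max - aoi$y_min) / rows
  col <- pmin(floor((fx$x_px - aoi$x_min) / cell_w), cols - 1L)
  row <- pmin(floor((fx$y_px - aoi$y_min) / cell_h), rows - 1L)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 row = as.integer(row), col = as.integer(col),
                 cell = as.integer(row * cols + col),
                 inside_fixations = nrow(fx),
                 total_fixations = nrow(fixations)),
            class = "grid_assignment")
}

#' Shannon entropy of the fixation distribution over grid cells
#'
#' `H = -sum(p_i * log(p_i))` over occupied cells, where `p_i` is the
#' fraction of inside fixations landing in cell `i`. With base-2 logs
#' (default) the result is in bits, bounded by `log2` of the number of
#' cells.
#'
#' @param assignment A `grid_assignment`.
#' @param log_base Logarithm base (default 2).
#' @return Entropy, or `NA` when there are no inside fixations.
#' @export
grid_entropy <- function(assignment, log_base = 2) {
  n <- assignment$inside_fixations
  if (n < 1L) return(NA_real_)
  p <- tabulate(assignment$cell + 1L,
                nbins = assignment$rows * assignment$cols) / n
  p <- p[p > 0]
  -sum(p * log(p, base = log_base))
}

#' Mean consecutive-fixation distance in grid-cell units
#'
#' The average Euclidean distance between consecutive inside fixations,
#' with the x component expressed in cell widths and the y component in
#' cell heights. Consecutive pairs never straddle trial boundaries when
#' `trial_id` is supplied.
#'
#' @param fixations Tibble with `x_px`, `y_px` in temporal order and
#'   optionally a `trial_id` column delimiting sequences.
#' @param aoi An [aoi_spec()].
#' @param rows,cols Grid dimensions defining the cell size.
#' @return Mean distance in cell units; `NA` with fewer than 2 fixations
#'   in every sequence.
#' @export
spatial_dispersion <- function(fixations, aoi, rows = 10L, cols = 10L) {
  cell_w <- (aoi$x_max - aoi$x_min) / cols
  cell_h <- (aoi$y_max - aoi$y_min) / rows
  d <- consecutive_pairs(fixations, function(a, b) {
    sqrt(((b$x_px - a$x_px) / cell_w)^2 + ((b$y_px - a$y_px) / cell_h)^2)
  })
  if (!length(d)) NA_real_ else mean(d)
}

#' Proportion of grid cells containing at least one fixation
#'
#' @param assignment A `grid_assignment`.
#' @return Fraction in `[0, 1]`; 0 when there are no inside fixations.
#' @export
grid_occupancy <- function(assignment) {
  if (assignment$inside_fixations < 1L) return(0)
  length(unique(assignment$cell)) / (assignment$rows * assignment$cols)
}

#' Ratio of unique to total inter-cell transitions
#'
#' A transition is an ordered pair (cell of fixation i, cell of fixation
#' i + 1) with distinct cells; within-cell steps are excluded from both
#' counts. The density is the number of distinct ordered pairs over the
#' number of observed inter-cell transitions, so revisiting the same route
#' lowers it.
#'
#' @param assignment A `grid_assignment` (fixation order preserved).
#' @param trial_id Optional vector parallel to the inside fixations;
#'   transitions never straddle trial boundaries.
#' @return Fraction in `(0, 1]`, or `NA` when no inter-cell transition
#'   exists.
#' @export
transition_density <- function(assignment, trial_id = NULL) {
  cell <- assignment$cell
  n <- length(cell)
  if (n < 2L) return(NA_real_)
  from <- cell[-n]; to <- cell[-1L]
  keep <- rep(TRUE, n - 1L)
  if (!is.null(trial_id)) keep <- trial_id[-n] == trial_id[-1L]
  keep <- keep & from != to
  if (!any(keep)) return(NA_real_)
  pairs <- paste(from[keep], to[keep])
  length(unique(pairs)) / length(pairs)
}

#' Clark-Evans nearest-neighbor index of fixation locations
#'
#' The observed mean distance from each fixation to its nearest other
#' fixation, divided by the expectation under complete spatial randomness
#' in a region of area `A`: `0.5 * sqrt(A / n)`. Values below 1 indicate
#' clustering, above 1 dispersion; coincident points give 0.
#'
#' @param fixations Tibble with `x_px`, `y_px` (inside fixations).
#' @param aoi An [aoi_spec()] whose rectangle supplies `A` (in px^2, the
#'   same units as the pixel distances).
#' @return The index, or `NA` with fewer than 2 fixations.
#' @export
nearest_neighbor_index <- function(fixations, aoi) {
  n <- nrow(fixations)
  if (n < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(cbind(fixations$x_px, fixations$y_px)))
  diag(d) <- Inf
  obs <- mean(apply(d, 1L, min))
  area <- (aoi$x_max - aoi$x_min) * (aoi$y_max - aoi$y_min)
  obs / (0.5 * sqrt(area / n))
}

#' Grid summary table per item x group cell
#'
#' Pools AOI fixations over participants within each (response type, item,
#' group) cell and computes the five grid statistics plus the inside
#' fixation count, in the layout of a grid-based results table. Sequential
#' statistics (spatial dispersion, transition density) respect trial
#' boundaries within the pool.
#'
#' @param events Event tibble from [preprocess_trials()].
#' @param trials Trial table from [read_trial_table()].
#' @param config A [pipeline_config()] supplying AOI, grid dimensions and
#'   entropy base.
#' @return Tibble: `response_type, item, group, inside_fixations,
#'   grid_entropy, spatial_dispersion, grid_occupancy, transition_density,
#'   nni`.
#' @export
summarize_grid <- function(events, trials, config = pipeline_config()) {
  fx <- events[events$kind == "fixation", ]
  fx <- dplyr::inner_join(fx, trials, by = "trial_id")
  fx$response_type <- ifelse(fx$response_correct == 1L, "correct", "incorrect")
  cells <- dplyr::distinct(fx[c("response_type", "item", "group")])
  cells <- dplyr::arrange(cells, .data$response_type, .data$item, .data$group)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- fx[fx$response_type == cells$response_type[i] &
                fx$item == cells$item[i] & fx$group == cells$group[i], ]
    sel <- sel[in_aoi(sel$x_px, sel$y_px, config$aoi), ]
    dplyr::bind_cols(cells[i, ], grid_cell_summary(sel, config))
  })
  dplyr::bind_rows(rows)
}

grid_cell_summary <- function(fixations, config) {
  asg <- assign_grid(fixations, config$aoi, config$grid_rows, config$grid_cols)
  tibble::tibble(
    inside_fixations = asg$inside_fixations,
    grid_entropy = grid_entropy(asg, config$entropy_log_base),
    spatial_dispersion = spatial_dispersion(fixations, config$aoi,
                                            config$grid_rows, config$grid_cols),
    grid_occupancy = if (asg$inside_fixations) grid_occupancy(asg) else NA_real_,
    transition_density = transition_density(asg, fixations$trial_id),
    nni = nearest_neighbor_index(fixations, config$aoi)
  )
}

# Apply f to consecutive fixation pairs, never across trial boundaries.
consecutive_pairs <- function(fixations, f) {
  n <- nrow(fixations)
  if (n < 2L) return(numeric())
  a <- fixations[-n, ]; b <- fixations[-1L, ]
  vals <- f(a, b)
  if ("trial_id" %in% names(fixations))
    vals <- vals[a$trial_id == b$trial_id]
  vals
}
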