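#' Rendering parameters for heatmaps and scanpaths
#'
#' @param width_px,height_px Canvas size in pixels (default full screen).
#' @param kernel_sigma_px Gaussian smoothing bandwidth of the heatmap.
#' @param duration_weighting Weight each fixation by its duration (TRUE,
#'   default) or count every fixation equally.
#' @param colormap Name of a viridis option for the fill scale.
#' @param downsample Integer factor by which the density grid is coarser
#'   than the canvas (default 4; 1 = per-pixel).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(width_px = 1920L, height_px = 1080L,
                        kernel_sigma_px = 50, duration_weighting = TRUE,
                        colormap = "inferno", downsample = 4L) {
  stopifnot(kernel_sigma_px > 0, width_px >= 1, height_px >= 1,
            downsample >= 1)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 kernel_sigma_px = kernel_sigma_px,
                 duration_weighting = isTRUE(duration_weighting),
                 colormap = colormap, downsample = as.integer(downsample)),
            class = "render_spec")
}

#' Fixation heatmap
#'
#' Sums an isotropic Gaussian kernel over fixation locations, each kernel
#' normalised to unit mass on the (possibly clipped) canvas and weighted by
#' fixation duration when `duration_weighting` is on — so the integrated
#' density equals the total (weighted) fixation count exactly, and the
#' field is linear in its inputs. The numeric density matrix is returned
#' alongside the plot so downstream checks never depend on image bytes.
#'
#' @param fixations Tibble with `x_px`, `y_px` and (for duration
#'   weighting) `t_start_ms`/`t_end_ms`.
#' @param spec A [render_spec()].
#' @return A list of class `gaze_heatmap`: `$density` (rows = y bins,
#'   cols = x bins), `$x`, `$y` (bin centres in px), `$plot` (ggplot).
#' @export
render_heatmap <- function(fixations, spec = render_spec()) {
  ds <- spec$downsample
  xg <- seq(ds / 2, spec$width_px - ds / 2, by = ds)
  yg <- seq(ds / 2, spec$height_px - ds / 2, by = ds)
  dens <- matrix(0, nrow = length(yg), ncol = length(xg))
  n <- nrow(fixations)
  if (n > 0) {
    w <- if (spec$duration_weighting)
      fixations$t_end_ms - fixations$t_start_ms
    else rep(1, n)
    for (i in seq_len(n)) {
      kx <- stats::dnorm(xg, fixations$x_px[i], spec$kernel_sigma_px)
      ky <- stats::dnorm(yg, fixations$y_px[i], spec$kernel_sigma_px)
      k <- outer(ky, kx)
      s <- sum(k)
      if (s > 0) dens <- dens + w[i] * k / s
    }
  }
  df <- expand.grid(x = xg, y = yg)
  df$z <- as.vector(t(dens))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = spec$colormap, name = "density") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  structure(list(density = dens, x = xg, y = yg, plot = p),
            class = "gaze_heatmap")
}

#' Scanpath plot
#'
#' Fixations as circles whose radius grows with duration, numbered in
#' temporal order; saccades as straight segments between the snapped
#' fixation coordinates. The ordered polyline through the fixation centres
#' is returned so that its total length can be checked against the trial's
#' scanpath-total metric.
#'
#' @param stream An `event_stream`.
#' @param spec A [render_spec()].
#' @return A list of class `gaze_scanpath`: `$polyline` (tibble `x_px`,
#'   `y_px` in fixation order; n - 1 segments), `$plot` (ggplot).
#' @export
render_scanpath <- function(stream, spec = render_spec()) {
  fx <- stream$fixations
  poly <- tibble::tibble(x_px = fx$x_px, y_px = fx$y_px)
  fx_df <- tibble::tibble(
    x = fx$x_px, y = fx$y_px,
    dur = fx$t_end_ms - fx$t_start_ms,
    ord = seq_len(nrow(fx)))
  p <- ggplot2::ggplot(fx_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::xlim(0, spec$width_px) +
    ggplot2::scale_y_reverse(limits = c(spec$height_px, 0)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (nrow(fx_df) > 1) {
    seg <- tibble::tibble(x = fx_df$x[-nrow(fx_df)], y = fx_df$y[-nrow(fx_df)],
                          xend = fx_df$x[-1], yend = fx_df$y[-1])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      color = "grey40", inherit.aes = FALSE)
  }
  if (nrow(fx_df) > 0) {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(size = .data$dur), alpha = 0.5,
                          color = "#2166ac") +
      ggplot2::geom_text(ggplot2::aes(label = .data$ord), size = 3) +
      ggplot2::scale_size_continuous(name = "duration (ms)")
  }
  structure(list(polyline = poly, plot = p), class = "gaze_scanpath")
}

#' Total length of a scanpath polyline
#'
#' @param polyline Tibble with `x_px`, `y_px` in order.
#' @return Summed Euclidean segment length in pixels (0 for < 2 points).
#' @export
polyline_length <- function(polyline) {
  n <- nrow(polyline)
  if (n < 2L) return(0)
  sum(sqrt(diff(polyline$x_px)^2 + diff(polyline$y_px)^2))
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat("<gaze_heatmap> ", nrow(x$density), "x", ncol(x$density),
      " density grid, total mass ", format(sum(x$density)), "\n", sep = "")
  invisible(x)
}

#' @export
print.gaze_scanpath <- function(x, ...) {
  cat("<gaze_scanpath> ", nrow(x$polyline), " fixation(s), path length ",
      format(polyline_length(x$polyline)), " px\n", sep = "")
  invisible(x)
}
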