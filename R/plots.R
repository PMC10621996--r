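#' Plot one frame of a synthetic scene
#'
#' @param object A `lyso_scene`.
#' @param frame Frame to show.
#' @param channel `"lyso"` or `"er"`.
#' @param ... Unused.
#' @return A ggplot raster of the frame with ground-truth centroids
#'   overlaid.
#' @method autoplot lyso_scene
#' @export
autoplot.lyso_scene <- function(object, frame = 1, channel = c("lyso", "er"),
                                ...) {
  channel <- match.arg(channel)
  img <- object[[channel]][, , frame]
  px_um <- object$config$pixel_size_nm / 1000
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))  # row-major to match (y, x) grid
  tr <- dplyr::filter(object$truth, .data$frame == !!frame)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$x - 1) * px_um,
                                   y = (.data$y - 1) * px_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = tr,
                        ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                     colour = .data$shape_class),
                        shape = 1, size = 3, inherit.aes = FALSE) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "truth", fill = channel)
}

#' Plot linked trajectories
#'
#' @param object A `lyso_tracks` tibble from [link_particles()].
#' @param ... Unused.
#' @return A ggplot of trajectory paths coloured by track.
#' @method autoplot lyso_tracks
#' @export
autoplot.lyso_tracks <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, group = .data$track,
                               colour = factor(.data$track))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "track")
}

#' Plot a kymograph
#'
#' Time runs downwards; the soma end of the path is at position 0, so
#' rightward-sloping traces are anterograde.
#'
#' @param object A `kymograph` from [build_kymograph()].
#' @param ... Unused.
#' @return A ggplot raster (position vs time).
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  step <- attr(object, "step_um")
  dt <- attr(object, "frame_interval_s")
  df <- tidyr::expand_grid(t = seq_len(nrow(object)),
                           s = seq_len(ncol(object)))
  df$intensity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes((.data$s - 1) * step, (.data$t - 1) * dt,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "distance from soma (µm)", y = "time (s)",
                  fill = "I")
}

#' Screen scatter of the two readouts with gate lines
#'
#' @param records Scored (and optionally gated) screen records.
#' @param gates Optional gates from [derive_gates()], drawn as dashed
#'   lines.
#' @return A ggplot: tubulation index vs mean knockout probability, hits
#'   highlighted when present.
#' @export
plot_screen <- function(records, gates = NULL) {
  p <- ggplot2::ggplot(as_tibble(records),
                       ggplot2::aes(.data$mean_ko_probability,
                                    .data$tubulation_index)) +
    ggplot2::labs(x = "mean knockout probability", y = "tubulation index")
  p <- if ("is_hit" %in% names(records)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$is_hit)) +
      ggplot2::labs(colour = "hit")
  } else {
    p + ggplot2::geom_point()
  }
  if (!is.null(gates)) {
    p <- p +
      ggplot2::geom_vline(xintercept = gates$nn_min_probability,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = gates$tub_max_index,
                          linetype = "dashed")
  }
  p
}

#' @export
print.lyso_scene <- function(x, ...) {
  d <- dim(x$lyso)
  cat(sprintf(
    "<lyso_scene> %d x %d px, %d frame(s), %d object(s) (%d round / %d tubular)\n",
    d[1], d[2], d[3], x$config$n_round + x$config$n_tubular,
    x$config$n_round, x$config$n_tubular))
  cat(sprintf("  pixel %g nm, interval %g s, seed %s\n",
              x$config$pixel_size_nm, x$config$frame_interval_s,
              format(x$config$seed)))
  invisible(x)
}

#' @export
print.axon_scene <- function(x, ...) {
  cat(sprintf("<axon_scene> %g µm axon, %d lysosome(s), %d frames @ %g s\n",
              x$config$axon_length_um, x$config$n_lysosomes,
              x$config$n_frames, x$config$frame_interval_s))
  invisible(x)
}
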