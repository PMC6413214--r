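#' Plot the 16-channel target representation
#'
#' Facets the four part heatmaps and, optionally, the twelve association
#' channels (shown in offset pixels). Useful for eyeballing encodings and
#' network outputs.
#'
#' @param object a `target_maps` object.
#' @param channels `"part"` or `"all"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.target_maps <- function(object, channels = c("part", "all"), ...) {
  channels <- match.arg(channels)
  size <- object$image_size
  grid <- tidyr::expand_grid(y = 0:(size[1] - 1), x = 0:(size[2] - 1))
  frames <- purrr::map(1:4, function(ch) {
    dplyr::mutate(grid, value = as.vector(object$part[, , ch]),
                  channel = paste0("part: ", part_types()[ch]))
  })
  if (channels == "all") {
    ac <- assoc_channels()
    frames <- c(frames, purrr::map(seq_len(nrow(ac)), function(k) {
      dplyr::mutate(grid,
                    value = as.vector(object$assoc[, , ac$x_channel[k]]),
                    channel = paste0(ac$from[k], "→", ac$to[k], " dx"))
    }))
  }
  df <- dplyr::bind_rows(frames)
  df$channel <- factor(df$channel, levels = unique(df$channel))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
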