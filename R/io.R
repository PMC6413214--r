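#' Read and write annotation files
#'
#' Annotations are stored as JSON:
#' `{"image": "f.png", "size": [R, C], "mask": [[x, y], ...],`
#' `"pigs": [{"id": 1, "shoulder": [x, y], "tail": [x, y],`
#' `"left_ear": [x, y] | null, "right_ear": [x, y] | null}, ...]}`.
#' Coordinates are in the working image space (0-based, x = column). The
#' reader validates the schema strictly and names the offending field
#' rather than coercing malformed values; `write_annotations()` /
#' `read_annotations()` round-trip losslessly.
#'
#' @param path file path.
#' @param frame a [frame_annotation()].
#' @param image optional image filename stored alongside the annotation.
#' @return `read_annotations()` returns a [frame_annotation()];
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  get_num2 <- function(v, field, nullable = FALSE) {
    if (is.null(v)) {
      if (nullable) return(c(NA_real_, NA_real_))
      stop("annotation schema: missing required field '", field, "'")
    }
    v <- unlist(v)
    if (length(v) != 2 || !is.numeric(v) || any(!is.finite(v))) {
      stop("annotation schema: field '", field, "' must be two finite numbers")
    }
    as.numeric(v)
  }
  if (is.null(doc$size)) stop("annotation schema: missing required field 'size'")
  size <- unlist(doc$size)
  if (length(size) != 2 || !is.numeric(size)) {
    stop("annotation schema: field 'size' must be [rows, cols]")
  }
  mask <- NULL
  if (!is.null(doc$mask)) {
    mask <- do.call(rbind, purrr::map(doc$mask, function(p) get_num2(p, "mask")))
  }
  pigs <- dplyr::bind_rows(purrr::imap(doc$pigs, function(p, i) {
    sh <- get_num2(p$shoulder, paste0("pigs[", i, "].shoulder"))
    tl <- get_num2(p$tail, paste0("pigs[", i, "].tail"))
    le <- get_num2(p$left_ear, paste0("pigs[", i, "].left_ear"), nullable = TRUE)
    re <- get_num2(p$right_ear, paste0("pigs[", i, "].right_ear"), nullable = TRUE)
    tibble::tibble(
      instance_id = if (is.null(p$id)) i else as.integer(p$id),
      shoulder_x = sh[1], shoulder_y = sh[2], tail_x = tl[1], tail_y = tl[2],
      left_ear_x = le[1], left_ear_y = le[2],
      right_ear_x = re[1], right_ear_y = re[2]
    )
  }))
  if (length(doc$pigs) == 0) pigs <- NULL
  frame_annotation(pigs, size, mask)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(frame, path, image = NULL) {
  frame <- as_frame_annotation(frame)
  pt <- function(x, y) if (is.na(x) || is.na(y)) NULL else c(x, y)
  pigs <- purrr::map(seq_len(nrow(frame)), function(i) {
    list(
      id = frame$instance_id[i],
      shoulder = c(frame$shoulder_x[i], frame$shoulder_y[i]),
      tail = c(frame$tail_x[i], frame$tail_y[i]),
      left_ear = pt(frame$left_ear_x[i], frame$left_ear_y[i]),
      right_ear = pt(frame$right_ear_x[i], frame$right_ear_y[i])
    )
  })
  doc <- list(size = image_size(frame), pigs = pigs)
  if (!is.null(image)) doc$image <- image
  mp <- mask_polygon(frame)
  if (!is.null(mp)) doc$mask <- unname(apply(mp, 1, c, simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write detected instances
#'
#' JSON uses the annotation dialect plus a `confidence` field per instance;
#' CSV is one row per instance with the flat coordinate columns.
#'
#' @param detections a [detection_set()].
#' @param path output file.
#' @param format `"json"` or `"csv"` (default chosen from the extension).
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path,
                             format = if (grepl("\\.csv$", path)) "csv" else "json") {
  if (format == "csv") {
    utils::write.csv(tibble::as_tibble(detections), path, row.names = FALSE)
    return(invisible(path))
  }
  pt <- function(x, y) if (is.na(x) || is.na(y)) NULL else c(x, y)
  pigs <- purrr::map(seq_len(nrow(detections)), function(i) {
    list(
      id = detections$instance_id[i],
      shoulder = c(detections$shoulder_x[i], detections$shoulder_y[i]),
      tail = c(detections$tail_x[i], detections$tail_y[i]),
      left_ear = pt(detections$left_ear_x[i], detections$left_ear_y[i]),
      right_ear = pt(detections$right_ear_x[i], detections$right_ear_y[i]),
      confidence = detections$confidence[i]
    )
  })
  doc <- list(size = attr(detections, "image_size", exact = TRUE), pigs = pigs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and write images
#'
#' Thin PNG wrappers returning `[R, C, 3]` arrays in `[0, 1]` under the
#' package's row/column convention.
#'
#' @param path file path.
#' @param image `[R, C, 3]` (or `[R, C]`) array in `[0, 1]`.
#' @return `read_image()` an array; `write_image()` `path` invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Mask and downsample an image to the working resolution
#'
#' Pixels outside the pen-boundary polygon are set to pure black, then the
#' image is resized (aspect-preserving, bilinear) so that it has
#' `target_cols` columns -- the working scale at which all annotations,
#' kernels and thresholds are defined. Annotations captured at the original
#' resolution must be multiplied by the returned `scale`.
#'
#' @param image `[R, C, 3]` array.
#' @param mask optional two-column (x, y) polygon in input pixel
#'   coordinates.
#' @param target_cols output column count (default 480).
#' @return List with `image` (resized array), `scale` (the factor applied
#'   to both axes) and `size` (output `c(rows, cols)`).
#' @export
preprocess_image <- function(image, mask = NULL, target_cols = 480L) {
  d <- dim(image)
  if (!is.null(mask)) {
    if (nrow(mask) < 3) stop("degenerate mask polygon: need at least 3 vertices")
    xs <- rep(0:(d[2] - 1), each = d[1])
    ys <- rep(0:(d[1] - 1), times = d[2])
    inside <- matrix(pracma::inpolygon(xs, ys, mask[, 1], mask[, 2]), d[1], d[2])
    for (ch in seq_len(d[3])) {
      sl <- image[, , ch]
      sl[!inside] <- 0
      image[, , ch] <- sl
    }
  }
  scale <- target_cols / d[2]
  rows_out <- as.integer(round(d[1] * scale))
  if (scale != 1) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("preprocess_image resizing requires the EBImage package")
    }
    # EBImage works width-first
    eb <- EBImage::resize(aperm(image, c(2, 1, 3)), w = target_cols, h = rows_out)
    image <- aperm(eb, c(2, 1, 3))
  }
  list(image = image, scale = scale, size = c(rows_out, as.integer(target_cols)))
}

#' Rescale annotation coordinates
#'
#' @param frame a [frame_annotation()] in original coordinates.
#' @param scale factor from [preprocess_image()].
#' @param size new image size `c(rows, cols)`.
#' @return A rescaled [frame_annotation()].
#' @export
scale_annotations <- function(frame, scale, size) {
  frame <- as_frame_annotation(frame)
  pigs <- tibble::as_tibble(frame)
  for (nm in setdiff(names(pigs), "instance_id")) pigs[[nm]] <- pigs[[nm]] * scale
  mp <- mask_polygon(frame)
  if (!is.null(mp)) mp <- mp * scale
  frame_annotation(pigs, size, mp)
}

#' Plot a scene with its annotations or detections
#'
#' @param image `[R, C, 3]` array (or `NULL` to plot annotations alone).
#' @param frame a [frame_annotation()] or [detection_set()].
#' @return A ggplot object with y increasing downwards, one segment per
#'   animal from shoulder to tail.
#' @export
plot_scene <- function(image = NULL, frame = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    d <- dim(image)
    df <- tidyr::expand_grid(y = 0:(d[1] - 1), x = 0:(d[2] - 1))
    df$fill <- grDevices::rgb(image[, , 1], image[, , 2], image[, , 3])
    p <- p + ggplot2::geom_raster(data = df, ggplot2::aes(.data$x, .data$y),
                                  fill = df$fill)
  }
  if (!is.null(frame) && nrow(frame) > 0) {
    df <- tibble::as_tibble(frame)
    p <- p +
      ggplot2::geom_segment(
        data = df,
        ggplot2::aes(x = .data$shoulder_x, y = .data$shoulder_y,
                     xend = .data$tail_x, yend = .data$tail_y),
        colour = "yellow", linewidth = 0.8
      ) +
      ggplot2::geom_point(
        data = df,
        ggplot2::aes(x = .data$shoulder_x, y = .data$shoulder_y),
        colour = "cyan", size = 1.6
      )
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() + ggplot2::theme_void()
}
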