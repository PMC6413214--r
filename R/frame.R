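#' Per-frame keypoint annotations
#'
#' A frame annotation is a tibble with one row per animal and the columns
#' `instance_id`, `shoulder_x`, `shoulder_y`, `tail_x`, `tail_y`,
#' `left_ear_x`, `left_ear_y`, `right_ear_x`, `right_ear_y`. Shoulder and
#' tail are required for every instance; ears may be `NA` (they are simply
#' not annotated when not visible). The image size (rows, cols) and an
#' optional pen mask polygon travel as attributes.
#'
#' Coordinates are 0-based with `x` indexing columns and `y` indexing rows,
#' pixel centres at integer coordinates; all points must lie inside
#' `[0, C) x [0, R)`.
#'
#' @param pigs a data frame with the columns above (missing ear columns are
#'   added as `NA`; a missing `instance_id` is filled with the row number).
#' @param image_size integer vector `c(rows, cols)`.
#' @param mask_polygon optional two-column matrix (x, y) of pen-boundary
#'   polygon vertices, or `NULL` for no mask.
#' @return A tibble of class `frame_annotation`.
#' @export
#' @examples
#' frame_annotation(
#'   tibble::tibble(shoulder_x = 50, shoulder_y = 40, tail_x = 90, tail_y = 40),
#'   image_size = c(120, 160)
#' )
frame_annotation <- function(pigs = NULL, image_size, mask_polygon = NULL) {
  cols <- c(
    "instance_id",
    "shoulder_x", "shoulder_y", "tail_x", "tail_y",
    "left_ear_x", "left_ear_y", "right_ear_x", "right_ear_y"
  )
  if (is.null(pigs) || nrow(pigs) == 0) {
    pigs <- tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(numeric(0)), 8)), cols
    ))
  } else {
    pigs <- tibble::as_tibble(pigs)
    if (!"instance_id" %in% names(pigs)) pigs$instance_id <- seq_len(nrow(pigs))
    for (nm in setdiff(cols, names(pigs))) pigs[[nm]] <- NA_real_
    pigs <- pigs[cols]
    for (nm in cols[-1]) pigs[[nm]] <- as.numeric(pigs[[nm]])
  }
  out <- tibble::new_tibble(
    pigs,
    image_size = as.integer(image_size),
    mask_polygon = mask_polygon,
    class = "frame_annotation"
  )
  validate_frame(out)
  out
}

#' @rdname frame_annotation
#' @param x an object to coerce / test.
#' @export
as_frame_annotation <- function(x) {
  if (inherits(x, "frame_annotation")) return(x)
  stop("expected a frame_annotation; got ", paste(class(x), collapse = "/"))
}

#' @rdname frame_annotation
#' @export
is_frame_annotation <- function(x) inherits(x, "frame_annotation")

#' @rdname frame_annotation
#' @export
image_size <- function(x) attr(x, "image_size", exact = TRUE)

#' @rdname frame_annotation
#' @export
mask_polygon <- function(x) attr(x, "mask_polygon", exact = TRUE)

#' Validate a frame annotation
#'
#' Checks the structural invariants: required shoulder/tail coordinates are
#' finite, ear coordinates are finite where present, all points lie inside
#' the image, and instance ids are unique. Degenerate instances with
#' `shoulder == tail` are tolerated here (they arise in raw annotation files)
#' but rejected later by the target encoder.
#'
#' @param frame a [frame_annotation()].
#' @return `frame`, invisibly; errors on violation.
#' @export
validate_frame <- function(frame) {
  size <- image_size(frame)
  if (is.null(size) || length(size) != 2 || any(size <= 0)) {
    stop("frame_annotation needs a positive image_size = c(rows, cols)")
  }
  if (nrow(frame) == 0) return(invisible(frame))
  if (anyDuplicated(frame$instance_id)) stop("instance_ids must be unique within a frame")
  req <- c("shoulder_x", "shoulder_y", "tail_x", "tail_y")
  for (nm in req) {
    if (!all(is.finite(frame[[nm]]))) stop("required coordinate '", nm, "' is missing or non-finite")
  }
  r <- size[1]; c <- size[2]
  inside <- function(x, y) x >= 0 & x < c & y >= 0 & y < r
  if (!all(inside(frame$shoulder_x, frame$shoulder_y)) ||
      !all(inside(frame$tail_x, frame$tail_y))) {
    stop("shoulder/tail coordinates outside image bounds [0,", c, ") x [0,", r, ")")
  }
  for (ear in c("left_ear", "right_ear")) {
    x <- frame[[paste0(ear, "_x")]]; y <- frame[[paste0(ear, "_y")]]
    present <- !is.na(x) | !is.na(y)
    if (any(present & (is.na(x) | is.na(y)))) stop(ear, " has one coordinate missing")
    if (any(present & !inside(x, y), na.rm = TRUE)) {
      stop(ear, " coordinates outside image bounds")
    }
  }
  invisible(frame)
}

# extract part coordinates c(x, y) of row i, or NULL when the part is absent
part_point <- function(frame, i, part) {
  x <- frame[[paste0(part, "_x")]][i]
  y <- frame[[paste0(part, "_y")]][i]
  if (is.na(x) || is.na(y)) return(NULL)
  c(x, y)
}

#' @export
print.frame_annotation <- function(x, ...) {
  size <- image_size(x)
  cat(sprintf(
    "<frame_annotation> %d pig(s), image %d x %d%s\n",
    nrow(x), size[1], size[2],
    if (is.null(mask_polygon(x))) "" else ", masked pen"
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
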