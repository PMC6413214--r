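#' Size-adaptive Gaussian kernel widths
#'
#' The standard deviation of the Gaussian kernel marking each part of animal
#' `n` adapts to the animal sizes in the frame:
#' `sigma_n = 0.16 * (mu + delta_n)`, where `delta_n` is the shoulder-to-tail
#' length of instance `n` and `mu` is the mean shoulder-to-tail length over
#' all instances in the frame. The blend keeps unusual poses from shrinking a
#' kernel too far while still adapting to individual size variation.
#'
#' @param frame a [frame_annotation()] with at least one pig.
#' @param scale the empirical scale factor applied to `mu + delta_n`
#'   (default 0.16).
#' @return Numeric vector of per-instance standard deviations, in pixels.
#' @export
#' @examples
#' fr <- frame_annotation(
#'   tibble::tibble(shoulder_x = 50, shoulder_y = 40, tail_x = 150, tail_y = 40),
#'   image_size = c(240, 320)
#' )
#' compute_sigma(fr) # 0.16 * (100 + 100) = 32
compute_sigma <- function(frame, scale = 0.16) {
  frame <- as_frame_annotation(frame)
  delta <- body_lengths(frame)
  if (length(delta) == 0) stop("cannot compute kernel sizes for an empty frame")
  if (any(delta <= .Machine$double.eps)) {
    stop("degenerate instance(s) with shoulder == tail: ",
         paste(frame$instance_id[delta <= .Machine$double.eps], collapse = ", "))
  }
  scale * (mean(delta) + delta)
}

# disc radius where a unit-peak Gaussian of width sigma falls to `level`
region_radius <- function(sigma, level = 0.2) {
  sigma * sqrt(-2 * log(level))
}

# bounding box of a kernel support, clipped to the image; NULL if empty
kernel_box <- function(center, radius, size) {
  x0 <- max(0L, as.integer(floor(center[1] - radius)))
  x1 <- min(size[2] - 1L, as.integer(ceiling(center[1] + radius)))
  y0 <- max(0L, as.integer(floor(center[2] - radius)))
  y1 <- min(size[1] - 1L, as.integer(ceiling(center[2] + radius)))
  if (x0 > x1 || y0 > y1) return(NULL)
  list(x = x0:x1, y = y0:y1)
}

# unit-peak Gaussian values on the integer grid of a kernel_box
kernel_values <- function(center, sigma, box) {
  dx2 <- (box$x - center[1])^2
  dy2 <- (box$y - center[2])^2
  exp(-(outer(dy2, dx2, `+`)) / (2 * sigma^2))
}

#' Render the four part heatmap channels
#'
#' Each annotated part of each instance is written into its channel as an
#' isotropic 2D Gaussian `exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma_n^2))`,
#' scaled so the magnitude at the centre is 1.0. Where two kernels of the
#' same part type overlap, the channel takes the pointwise maximum. Kernels
#' are truncated at 4 sigma (dropped values < 3.4e-4, far below every
#' decoder threshold). Missing ears contribute nothing.
#'
#' @param frame a [frame_annotation()].
#' @param sigma per-instance kernel widths from [compute_sigma()].
#' @return Array `[R, C, 4]` with values in `[0, 1]`, channels in
#'   [part_types()] order.
#' @export
render_part_maps <- function(frame, sigma = compute_sigma(frame)) {
  frame <- as_frame_annotation(frame)
  size <- image_size(frame)
  maps <- array(0, dim = c(size[1], size[2], 4L))
  for (i in seq_len(nrow(frame))) {
    for (part in part_types()) {
      pt <- part_point(frame, i, part)
      if (is.null(pt)) next
      box <- kernel_box(pt, 4 * sigma[i], size)
      if (is.null(box)) next
      ch <- part_channel(part)
      vals <- kernel_values(pt, sigma[i], box)
      sl <- maps[box$y + 1L, box$x + 1L, ch, drop = FALSE]
      maps[box$y + 1L, box$x + 1L, ch] <- pmax(sl[, , 1L], vals)
    }
  }
  maps
}

#' Render the twelve association vector channels
#'
#' For each directed part pair of each instance (left ear <-> shoulder,
#' right ear <-> shoulder, shoulder <-> tail), a constant offset vector
#' `from - to` fills the circular region around the source part where that
#' part's Gaussian kernel exceeds magnitude 0.2. A binary assignment mask
#' marks the filled pixels; the selective training loss only flows where the
#' mask is set. Where regions of the same channel from different instances
#' intersect, the stored vector is the kernel-magnitude-weighted average of
#' all contributing vectors (weights normalised to sum to one). Pairs with a
#' missing ear are skipped.
#'
#' @inheritParams render_part_maps
#' @param level kernel magnitude defining the assigned region (default 0.2).
#' @return List with `assoc` (array `[R, C, 12]`, pixel offsets) and `mask`
#'   (array `[R, C, 12]`, 0/1); `assoc` is exactly zero wherever `mask` is 0.
#' @export
render_assoc_maps <- function(frame, sigma = compute_sigma(frame), level = 0.2) {
  frame <- as_frame_annotation(frame)
  size <- image_size(frame)
  assoc <- array(0, dim = c(size[1], size[2], 12L))
  wsum <- array(0, dim = c(size[1], size[2], 12L))
  pairs <- assoc_channels()
  for (i in seq_len(nrow(frame))) {
    for (k in seq_len(nrow(pairs))) {
      from <- part_point(frame, i, pairs$from[k])
      to <- part_point(frame, i, pairs$to[k])
      if (is.null(from) || is.null(to)) next
      box <- kernel_box(from, region_radius(sigma[i], level), size)
      if (is.null(box)) next
      w <- kernel_values(from, sigma[i], box)
      w[w <= level] <- 0
      off <- from - to
      xi <- pairs$x_channel[k]; yi <- pairs$y_channel[k]
      assoc[box$y + 1L, box$x + 1L, xi] <- assoc[box$y + 1L, box$x + 1L, xi] + w * off[1]
      assoc[box$y + 1L, box$x + 1L, yi] <- assoc[box$y + 1L, box$x + 1L, yi] + w * off[2]
      wsum[box$y + 1L, box$x + 1L, xi] <- wsum[box$y + 1L, box$x + 1L, xi] + w
      wsum[box$y + 1L, box$x + 1L, yi] <- wsum[box$y + 1L, box$x + 1L, yi] + w
    }
  }
  mask <- (wsum > 0) + 0
  assoc <- ifelse(wsum > 0, assoc / pmax(wsum, .Machine$double.eps), 0)
  list(assoc = assoc, mask = mask)
}

#' Encode a frame annotation into the 16-channel target representation
#'
#' Composes [render_part_maps()] and [render_assoc_maps()] into a
#' `target_maps` object: 4 unit-peak Gaussian part channels, 12 association
#' vector channels and the binary assignment mask used by the selective
#' training loss. An empty frame encodes to all-zero maps.
#'
#' @inheritParams render_part_maps
#' @return A `target_maps` object: list with `part` `[R, C, 4]`, `assoc`
#'   `[R, C, 12]`, `mask` `[R, C, 12]`, `sigma` and `image_size`.
#' @export
encode_frame <- function(frame, sigma = NULL) {
  frame <- as_frame_annotation(frame)
  size <- image_size(frame)
  if (nrow(frame) == 0) {
    return(new_target_maps(
      part = array(0, c(size[1], size[2], 4L)),
      assoc = array(0, c(size[1], size[2], 12L)),
      mask = array(0, c(size[1], size[2], 12L)),
      sigma = numeric(0), image_size = size
    ))
  }
  if (is.null(sigma)) sigma <- compute_sigma(frame)
  am <- render_assoc_maps(frame, sigma)
  new_target_maps(
    part = render_part_maps(frame, sigma),
    assoc = am$assoc, mask = am$mask,
    sigma = sigma, image_size = size
  )
}

new_target_maps <- function(part, assoc, mask, sigma, image_size) {
  structure(
    list(part = part, assoc = assoc, mask = mask,
         sigma = sigma, image_size = as.integer(image_size)),
    class = "target_maps"
  )
}

#' @export
print.target_maps <- function(x, ...) {
  cat(sprintf(
    "<target_maps> %d x %d, 4 part + 12 association channels, %d instance kernel(s)\n",
    x$image_size[1], x$image_size[2], length(x$sigma)
  ))
  invisible(x)
}

#' Convert between target_maps and a plain 16-channel array
#'
#' Channel order in the flat array: parts 1-4 in [part_types()] order, then
#' the 12 association channels in [assoc_channels()] order. The assignment
#' mask is not part of the flat array (a network predicting the 16 channels
#' has no mask output); `as_target_maps()` reconstructs one as the nonzero
#' pattern only if `mask` is supplied.
#'
#' @param x a `target_maps` object or `[R, C, 16]` array.
#' @param mask optional `[R, C, 12]` mask when converting from an array.
#' @return `target_stack()` returns an `[R, C, 16]` array;
#'   `as_target_maps()` a `target_maps` object.
#' @export
target_stack <- function(x) {
  stopifnot(inherits(x, "target_maps"))
  out <- array(0, c(x$image_size[1], x$image_size[2], 16L))
  out[, , 1:4] <- x$part
  out[, , 5:16] <- x$assoc
  out
}

#' @rdname target_stack
#' @export
as_target_maps <- function(x, mask = NULL) {
  if (inherits(x, "target_maps")) return(x)
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] == 16)
  size <- dim(x)[1:2]
  if (is.null(mask)) mask <- array(1, c(size, 12L))
  new_target_maps(
    part = x[, , 1:4, drop = FALSE],
    assoc = x[, , 5:16, drop = FALSE],
    mask = mask, sigma = numeric(0), image_size = size
  )
}

#' Sample a map channel at integer coordinates
#'
#' Convenience accessor honouring the package coordinate convention
#' (0-based, x = column, y = row).
#'
#' @param map a 2D matrix (one channel).
#' @param x,y 0-based coordinates (vectors allowed).
#' @return Map values at the given pixels.
#' @export
map_value <- function(map, x, y) {
  map[cbind(y + 1L, x + 1L)]
}
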