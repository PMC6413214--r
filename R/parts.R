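#' Body part vocabulary
#'
#' Four named landmarks are annotated on the back surface of each animal as
#' seen from the top-down camera: the left ear, right ear, shoulder (a point
#' on the centre ridge between the shoulder blades) and tail (a point on the
#' centre ridge between the hams). Their order is fixed and defines the
#' channel layout of every 16-channel map: part `p` lives in part channel
#' `part_channel(p)`.
#'
#' @return `part_types()` returns the four part names in channel order.
#' @export
#' @examples
#' part_types()
#' part_channel("shoulder")
part_types <- function() {
  c("left_ear", "right_ear", "shoulder", "tail")
}

#' @rdname part_types
#' @param part character vector of part names.
#' @return `part_channel()` returns the 1-based part-map channel index.
#' @export
part_channel <- function(part) {
  idx <- match(part, part_types())
  if (anyNA(idx)) {
    stop("unknown part type(s): ", paste(setdiff(part, part_types()), collapse = ", "))
  }
  idx
}

#' Association channel layout
#'
#' The twelve association channels store pixel offsets between three part
#' pairs, bidirectionally. Within the 12-channel association block, channels
#' come in (x, y) pairs ordered: left ear -> shoulder, shoulder -> left ear,
#' right ear -> shoulder, shoulder -> right ear, shoulder -> tail,
#' tail -> shoulder. The channel pair for direction `from -> to` is filled in
#' a disc around `from` and stores the offset `from - to`, so that sampling
#' the pair at `from` and subtracting recovers the partner location `to`.
#'
#' @return A tibble with one row per directed pair: `from`, `to`, `x_channel`,
#'   `y_channel` (1-based indices into the 12-channel association block).
#' @export
#' @examples
#' assoc_channels()
assoc_channels <- function() {
  tibble::tibble(
    from = c("left_ear", "shoulder", "right_ear", "shoulder", "shoulder", "tail"),
    to   = c("shoulder", "left_ear", "shoulder", "right_ear", "tail", "shoulder"),
    x_channel = c(1L, 3L, 5L, 7L, 9L, 11L),
    y_channel = c(2L, 4L, 6L, 8L, 10L, 12L)
  )
}

# channel pair (x, y) within the association block for direction from -> to
assoc_pair <- function(from, to) {
  ch <- assoc_channels()
  row <- ch[ch$from == from & ch$to == to, ]
  if (nrow(row) != 1) stop("no association channels for pair ", from, " -> ", to)
  c(row$x_channel, row$y_channel)
}

#' Euclidean distance between two points
#'
#' Points use the package-wide image coordinate convention: `x` indexes
#' columns, `y` indexes rows, both 0-based with pixel centres at integer
#' coordinates. Sub-pixel (non-integer) coordinates are allowed.
#'
#' @param a,b numeric length-2 vectors `c(x, y)`.
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' euclidean_norm(c(0, 0), c(3, 4)) # 5
euclidean_norm <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Shoulder-to-tail body length of each annotated animal
#'
#' The body length of an instance is the Euclidean distance between its
#' shoulder and tail annotations; it drives the size-adaptive Gaussian kernel
#' widths used by the target encoder.
#'
#' @param frame a [frame_annotation()].
#' @return Numeric vector, one length per pig (empty for an empty frame).
#' @export
body_lengths <- function(frame) {
  frame <- as_frame_annotation(frame)
  if (nrow(frame) == 0) return(numeric(0))
  sqrt((frame$shoulder_x - frame$tail_x)^2 + (frame$shoulder_y - frame$tail_y)^2)
}
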