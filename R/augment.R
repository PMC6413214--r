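#' Augmentation specification and draws
#'
#' Joint spatial augmentation of an image and its target: random left-right
#' flips, rotations uniform in `[0, 360)` degrees, scaling uniform in
#' `[0.5, 1.5]`, and XY shifts uniform in `[-20, 20]` pixels per axis.
#' A *draw* is one concrete sample of these parameters; the same draw is
#' applied identically to the image and to either the annotation (which is
#' then re-encoded) or the rendered 16-channel maps.
#'
#' Rotation convention: angles are applied with the matrix
#' `[[cos, -sin], [sin, cos]]` in (x right, y down) image coordinates, i.e.
#' a positive angle rotates the +x axis towards +y (clockwise on screen).
#' All transforms are centred on the image centre; offset vectors stored in
#' the association channels transform by the same rotation/scale/flip but
#' are unaffected by shifts.
#'
#' @param flip_prob probability of a left-right flip.
#' @param rotation_range degrees, uniform.
#' @param scale_range multiplicative, uniform.
#' @param shift_range max absolute shift per axis, pixels.
#' @return `augment_spec()` returns an `augment_spec` list; `augment_draw()`
#'   a fixed draw built from explicit values; `draw_augment()` samples a
#'   draw from the spec using the current RNG state.
#' @export
augment_spec <- function(flip_prob = 0.5, rotation_range = c(0, 360),
                         scale_range = c(0.5, 1.5), shift_range = 20) {
  structure(
    list(flip_prob = flip_prob, rotation_range = rotation_range,
         scale_range = scale_range, shift_range = shift_range),
    class = "augment_spec"
  )
}

#' @rdname augment_spec
#' @param flip logical.
#' @param angle rotation in degrees.
#' @param scale scale factor.
#' @param shift numeric `c(dx, dy)` pixels.
#' @export
augment_draw <- function(flip = FALSE, angle = 0, scale = 1, shift = c(0, 0)) {
  structure(list(flip = flip, angle = angle, scale = scale, shift = shift),
            class = "augment_draw")
}

#' @rdname augment_spec
#' @param spec an `augment_spec`.
#' @export
draw_augment <- function(spec = augment_spec()) {
  augment_draw(
    flip = stats::runif(1) < spec$flip_prob,
    angle = stats::runif(1, spec$rotation_range[1], spec$rotation_range[2]),
    scale = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
    shift = stats::runif(2, -spec$shift_range, spec$shift_range)
  )
}

# 2x2 linear part of the draw (flip, then rotate, then scale)
draw_matrix <- function(draw) {
  th <- draw$angle * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  flip <- if (draw$flip) diag(c(-1, 1)) else diag(2)
  draw$scale * rot %*% flip
}

# forward point transform p -> M (p - ctr) + ctr + shift
draw_apply <- function(draw, pts, size) {
  ctr <- c((size[2] - 1) / 2, (size[1] - 1) / 2)
  M <- draw_matrix(draw)
  sweep(t(M %*% t(sweep(pts, 2, ctr))), 2, ctr + draw$shift, `+`)
}

#' Augment a frame annotation
#'
#' Applies the draw to every keypoint. A left-right flip swaps the left and
#' right ear labels (the mirror of a left ear *is* a right ear). Instances
#' whose shoulder or tail leaves the frame are dropped entirely; ears that
#' leave the frame are dropped individually.
#'
#' @param frame a [frame_annotation()].
#' @param draw an [augment_draw()].
#' @return A transformed [frame_annotation()] (same image size).
#' @export
augment_frame <- function(frame, draw) {
  frame <- as_frame_annotation(frame)
  size <- image_size(frame)
  if (nrow(frame) == 0) return(frame)
  tf <- function(xn, yn) {
    pts <- cbind(frame[[xn]], frame[[yn]])
    ok <- stats::complete.cases(pts)
    out <- matrix(NA_real_, nrow(pts), 2)
    if (any(ok)) out[ok, ] <- draw_apply(draw, pts[ok, , drop = FALSE], size)
    out
  }
  sh <- tf("shoulder_x", "shoulder_y"); tl <- tf("tail_x", "tail_y")
  le <- tf("left_ear_x", "left_ear_y"); re <- tf("right_ear_x", "right_ear_y")
  if (draw$flip) { tmp <- le; le <- re; re <- tmp }
  inb <- function(m) !is.na(m[, 1]) & m[, 1] >= 0 & m[, 1] < size[2] &
    m[, 2] >= 0 & m[, 2] < size[1]
  keep <- inb(sh) & inb(tl)
  drop_ear <- function(m) { m[!inb(m), ] <- NA_real_; m }
  le <- drop_ear(le); re <- drop_ear(re)
  pigs <- tibble::tibble(
    instance_id = frame$instance_id[keep],
    shoulder_x = sh[keep, 1], shoulder_y = sh[keep, 2],
    tail_x = tl[keep, 1], tail_y = tl[keep, 2],
    left_ear_x = le[keep, 1], left_ear_y = le[keep, 2],
    right_ear_x = re[keep, 1], right_ear_y = re[keep, 2]
  )
  frame_annotation(pigs, size, mask_polygon(frame))
}

# inverse-map spatial warp of one channel; fill value 0 outside
warp_channel <- function(mat, draw, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  r <- nrow(mat); c <- ncol(mat)
  ctr <- c((c - 1) / 2, (r - 1) / 2)
  Minv <- solve(draw_matrix(draw))
  xs <- rep(0:(c - 1), each = r) - ctr[1] - draw$shift[1]
  ys <- rep(0:(r - 1), times = c) - ctr[2] - draw$shift[2]
  sx <- Minv[1, 1] * xs + Minv[1, 2] * ys + ctr[1]
  sy <- Minv[2, 1] * xs + Minv[2, 2] * ys + ctr[2]
  out <- numeric(r * c)
  if (method == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= c - 1 & iy >= 0 & iy <= r - 1
    out[ok] <- mat[cbind(iy[ok] + 1, ix[ok] + 1)]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    val <- function(xx, yy) {
      ok <- xx >= 0 & xx <= c - 1 & yy >= 0 & yy <= r - 1
      v <- numeric(length(xx))
      v[ok] <- mat[cbind(yy[ok] + 1, xx[ok] + 1)]
      v
    }
    out <- (1 - fy) * ((1 - fx) * val(x0, y0) + fx * val(x0 + 1, y0)) +
      fy * ((1 - fx) * val(x0, y0 + 1) + fx * val(x0 + 1, y0 + 1))
  }
  matrix(out, r, c)
}

#' Augment an image
#'
#' Spatial warp of an `[R, C, 3]` (or single-channel) image array with
#' bilinear interpolation; pixels pulled from outside the source are black.
#'
#' @param image numeric array.
#' @param draw an [augment_draw()].
#' @return Warped array of the same shape.
#' @export
augment_image <- function(image, draw) {
  if (length(dim(image)) == 2) return(warp_channel(image, draw, "bilinear"))
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- warp_channel(image[, , ch], draw, "bilinear")
  }
  out
}

#' Augment rendered target maps in map space
#'
#' Warps all 16 channels (and the assignment mask) spatially, then fixes up
#' the channel semantics: a flip swaps the left/right part channels and the
#' left<->shoulder / right<->shoulder association groups and mirrors the
#' x offset components; rotation by the draw angle rotates every stored
#' (dx, dy) offset pair by the same angle; scaling multiplies stored offsets
#' by the scale factor; pure shifts leave offset values unchanged. Part
#' channels are warped bilinearly; association and mask channels use
#' nearest-neighbour sampling so constant vector regions are not blurred
#' across region boundaries. The annotation-space path
#' ([augment_frame()] + [encode_frame()]) is the default for training; this
#' map-space path exists for parity checking between the two.
#'
#' @param maps a `target_maps` object.
#' @param draw an [augment_draw()].
#' @return A transformed `target_maps` object.
#' @export
augment_maps <- function(maps, draw) {
  stopifnot(inherits(maps, "target_maps"))
  part <- maps$part; assoc <- maps$assoc; mask <- maps$mask
  for (ch in 1:4) part[, , ch] <- warp_channel(part[, , ch], draw, "bilinear")
  for (ch in 1:12) {
    assoc[, , ch] <- warp_channel(assoc[, , ch], draw, "nearest")
    mask[, , ch] <- warp_channel(mask[, , ch], draw, "nearest")
  }
  if (draw$flip) {
    part <- part[, , c(part_channel("right_ear"), part_channel("left_ear"),
                       part_channel("shoulder"), part_channel("tail"))]
    # swap the l<->s group (channels 1-4) with the r<->s group (5-8)
    assoc <- assoc[, , c(5:8, 1:4, 9:12)]
    mask <- mask[, , c(5:8, 1:4, 9:12)]
  }
  # transform the stored offsets: same linear map as the geometry
  M <- draw_matrix(draw)
  for (k in seq_len(6)) {
    xi <- 2 * k - 1; yi <- 2 * k
    ox <- assoc[, , xi]; oy <- assoc[, , yi]
    assoc[, , xi] <- M[1, 1] * ox + M[1, 2] * oy
    assoc[, , yi] <- M[2, 1] * ox + M[2, 2] * oy
  }
  assoc[mask == 0] <- 0
  new_target_maps(part, assoc, mask, maps$sigma * draw$scale, maps$image_size)
}

#' Augment an (image, target) pair jointly
#'
#' @param image image array.
#' @param target a [frame_annotation()] or `target_maps`.
#' @param draw an [augment_draw()]; when `NULL` a fresh draw is sampled
#'   from `spec`.
#' @param spec an [augment_spec()].
#' @return List with `image`, `target` and the `draw` used.
#' @export
augment_pair <- function(image, target, draw = NULL, spec = augment_spec()) {
  if (is.null(draw)) draw <- draw_augment(spec)
  out_target <- if (is_frame_annotation(target)) {
    augment_frame(target, draw)
  } else {
    augment_maps(target, draw)
  }
  list(image = augment_image(image, draw), target = out_target, draw = draw)
}

#' Check that augmentation and encoding commute
#'
#' Encodes the frame, warps the maps in map space, and compares against the
#' encoding of the transformed annotation: every surviving part must have
#' its warped Gaussian peak within `tol` pixels of the re-encoded peak, and
#' the association offsets sampled at each surviving part must agree within
#' `tol` pixels. This is the augmentation module's main oracle -- it ties
#' the two independent augmentation paths together.
#'
#' @param frame a [frame_annotation()].
#' @param draw an [augment_draw()].
#' @param tol tolerance in pixels.
#' @return Logical; attribute `"max_error"` carries the worst discrepancy.
#' @export
consistency_check <- function(frame, draw, tol = 0.5) {
  frame <- as_frame_annotation(frame)
  warped <- augment_maps(encode_frame(frame), draw)
  frame2 <- augment_frame(frame, draw)
  if (nrow(frame2) == 0) {
    return(structure(TRUE, max_error = 0))
  }
  enc2 <- encode_frame(frame2)
  max_err <- 0
  ok <- TRUE
  pairs <- assoc_channels()
  for (i in seq_len(nrow(frame2))) {
    for (part in part_types()) {
      pt <- part_point(frame2, i, part)
      if (is.null(pt)) next
      # peak location near the expected point; a tight window keeps a
      # neighbouring animal's kernel flank from out-scoring a warped
      # (interpolation-lowered) peak, and any commutation failure larger
      # than the window would blow the tolerance anyway
      pk_w <- local_peak_near(warped$part[, , part_channel(part)], pt, 3)
      pk_e <- local_peak_near(enc2$part[, , part_channel(part)], pt, 3)
      if (is.null(pk_w) || is.null(pk_e)) { ok <- FALSE; next }
      err <- euclidean_norm(pk_w, pk_e)
      max_err <- max(max_err, err)
      if (err >= tol) ok <- FALSE
    }
    # offsets sampled at each surviving source part
    for (k in seq_len(nrow(pairs))) {
      from <- part_point(frame2, i, pairs$from[k])
      to <- part_point(frame2, i, pairs$to[k])
      if (is.null(from) || is.null(to)) next
      est_w <- sample_association(warped$assoc, from, pairs$from[k], pairs$to[k])
      est_e <- sample_association(enc2$assoc, from, pairs$from[k], pairs$to[k])
      err <- euclidean_norm(est_w, est_e)
      max_err <- max(max_err, err)
      if (err >= tol) ok <- FALSE
    }
  }
  structure(ok, max_error = max_err)
}

# sub-pixel peak of `map` within a window around an expected location
local_peak_near <- function(map, pt, radius) {
  r <- nrow(map); c <- ncol(map)
  x0 <- max(0, floor(pt[1] - radius)); x1 <- min(c - 1, ceiling(pt[1] + radius))
  y0 <- max(0, floor(pt[2] - radius)); y1 <- min(r - 1, ceiling(pt[2] + radius))
  if (x0 > x1 || y0 > y1) return(NULL)
  sub <- map[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  if (max(sub) <= 0) return(NULL)
  w <- which.max(sub)
  iy <- (w - 1) %% nrow(sub); ix <- (w - 1) %/% nrow(sub)
  subpixel_refine(map, c(x0 + ix, y0 + iy))
}
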