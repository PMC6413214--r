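#' Decoder configuration
#'
#' Defaults reproduce the reference processing chain: a 5x5 averaging box
#' filter applied to all 16 channels, regional maximum detection over a
#' 15x15 window, and a part detection threshold of 0.25 applied to the four
#' part channels. `association_mode` selects how parts are grouped into
#' instances: `"vector"` uses the association vector distance; `"euclidean"`
#' is the ablation baseline that simply minimises Euclidean distance between
#' parts.
#'
#' @param detection_threshold part detection threshold in (0, 1).
#' @param peak_window odd width of the regional-maximum window (pixels).
#' @param smooth_kernel odd width of the averaging box filter; 1 disables
#'   smoothing.
#' @param association_mode `"vector"` or `"euclidean"`.
#' @param max_assignment_distance optional gate: assignments whose pair
#'   distance exceeds this are discarded after the Hungarian step. The
#'   default `Inf` (no gate) is the canonical behaviour -- the pipeline
#'   avoids resolution-dependent distance parameters and relies on the
#'   cross-check evaluation instead; the gate exists for practical use.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(detection_threshold = 0.25, peak_window = 15L,
                           smooth_kernel = 5L,
                           association_mode = c("vector", "euclidean"),
                           max_assignment_distance = Inf) {
  stopifnot(
    detection_threshold > 0, detection_threshold < 1,
    peak_window >= 1, peak_window %% 2 == 1,
    smooth_kernel >= 1, smooth_kernel %% 2 == 1,
    max_assignment_distance > 0
  )
  structure(
    list(
      detection_threshold = detection_threshold,
      peak_window = as.integer(peak_window),
      smooth_kernel = as.integer(smooth_kernel),
      association_mode = match.arg(association_mode),
      max_assignment_distance = max_assignment_distance
    ),
    class = "decoder_config"
  )
}

# normalized box filter with replicate padding
box_filter <- function(mat, k) {
  if (k == 1) return(mat)
  p <- k %/% 2
  r <- nrow(mat); c <- ncol(mat)
  ridx <- c(rep(1L, p), seq_len(r), rep(r, p))
  cidx <- c(rep(1L, p), seq_len(c), rep(c, p))
  pad <- mat[ridx, cidx, drop = FALSE]
  acc <- matrix(0, r, c)
  for (dy in 0:(k - 1)) {
    for (dx in 0:(k - 1)) {
      acc <- acc + pad[(1 + dy):(r + dy), (1 + dx):(c + dx), drop = FALSE]
    }
  }
  acc / (k * k)
}

#' Smooth all 16 channels with an averaging box filter
#'
#' Border pixels are handled with replicate padding. Smoothing is a no-op on
#' constants and (away from borders) on affine ramps; on network outputs it
#' suppresses pixel noise before regional maximum detection.
#'
#' @param maps a `target_maps` object or `[R, C, 16]` array.
#' @param k odd box width (default 5).
#' @return Object of the same type with every channel filtered.
#' @export
smooth_maps <- function(maps, k = 5L) {
  if (inherits(maps, "target_maps")) {
    for (ch in 1:4) maps$part[, , ch] <- box_filter(maps$part[, , ch], k)
    for (ch in 1:12) maps$assoc[, , ch] <- box_filter(maps$assoc[, , ch], k)
    return(maps)
  }
  stopifnot(is.array(maps), length(dim(maps)) == 3)
  for (ch in seq_len(dim(maps)[3])) maps[, , ch] <- box_filter(maps[, , ch], k)
  maps
}

# separable max filter over a centred w x w window, clipped at borders
# (-Inf padding makes the shifted maxima equal window clipping)
local_max_filter <- function(mat, w) {
  p <- w %/% 2
  r <- nrow(mat); c <- ncol(mat)
  out <- mat
  for (d in seq_len(p)) {
    sh <- matrix(-Inf, r, c)
    sh[seq_len(r - d), ] <- mat[(1 + d):r, , drop = FALSE]
    out <- pmax(out, sh)
    sh <- matrix(-Inf, r, c)
    sh[(1 + d):r, ] <- mat[seq_len(r - d), , drop = FALSE]
    out <- pmax(out, sh)
  }
  mat2 <- out
  for (d in seq_len(p)) {
    sh <- matrix(-Inf, r, c)
    sh[, seq_len(c - d)] <- mat2[, (1 + d):c, drop = FALSE]
    out <- pmax(out, sh)
    sh <- matrix(-Inf, r, c)
    sh[, (1 + d):c] <- mat2[, seq_len(c - d), drop = FALSE]
    out <- pmax(out, sh)
  }
  out
}

#' Regional maximum part detection
#'
#' A pixel is a peak when its value is greater than or equal to every value
#' in the centred `peak_window x peak_window` neighbourhood (clipped at the
#' image borders) and at least `detection_threshold`. Within a connected
#' plateau of tied maxima only the lexicographically smallest pixel
#' (by y, then x) is kept, so one physical peak yields one detection.
#'
#' @param part_map 2D matrix (one smoothed part channel).
#' @param config a [decoder_config()].
#' @return Matrix with columns `x`, `y` (0-based integer coordinates) and
#'   `value`; zero rows when nothing exceeds the threshold.
#' @export
detect_peaks <- function(part_map, config = decoder_config()) {
  lm <- local_max_filter(part_map, config$peak_window)
  cand <- which(part_map >= lm & part_map >= config$detection_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(cbind(x = integer(0), y = integer(0), value = numeric(0)))
  }
  # deduplicate plateaus: connected components (8-connectivity) over
  # candidate pixels, keeping the smallest (y, x)
  key <- (cand[, 1] - 1L) + nrow(part_map) * (cand[, 2] - 1L)
  cand_set <- new.env(hash = TRUE, size = length(key))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = cand_set)
  visited <- rep(FALSE, nrow(cand))
  r <- nrow(part_map); c <- ncol(part_map)
  peaks <- list()
  ord <- order(cand[, 1], cand[, 2]) # row-major lexicographic (y, x)
  for (s in ord) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE
    comp <- s
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      yy <- cand[i, 1]; xx <- cand[i, 2]
      for (dy in -1:1) for (dx in -1:1) {
        ny <- yy + dy; nx <- xx + dx
        if (ny < 1 || ny > r || nx < 1 || nx > c) next
        nk <- as.character((ny - 1L) + r * (nx - 1L))
        j <- get0(nk, envir = cand_set, ifnotfound = NULL)
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
          comp <- c(comp, j)
        }
      }
    }
    sub <- cand[comp, , drop = FALSE]
    best <- order(sub[, 1], sub[, 2])[1]
    peaks[[length(peaks) + 1L]] <- c(sub[best, 2] - 1L, sub[best, 1] - 1L)
  }
  pk <- do.call(rbind, peaks)
  cbind(x = pk[, 1], y = pk[, 2],
        value = part_map[cbind(pk[, 2] + 1L, pk[, 1] + 1L)])
}

#' Quadratic sub-pixel peak refinement
#'
#' Fits, independently per axis, a parabola through the three samples at
#' offsets -1, 0, +1 around the integer peak and moves the coordinate to the
#' parabola vertex: `delta = (v_minus - v_plus) / (2 (v_minus - 2 v_0 +
#' v_plus))`. The axis is left unrefined when the peak touches the image
#' border, the curvature is non-negative (no local maximum), or the vertex
#' overshoots half a pixel.
#'
#' @param part_map 2D matrix.
#' @param peak numeric `c(x, y)` integer 0-based peak location.
#' @return numeric `c(x, y)` refined coordinates.
#' @export
subpixel_refine <- function(part_map, peak) {
  x <- peak[1]; y <- peak[2]
  r <- nrow(part_map); c <- ncol(part_map)
  refine_axis <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den >= 0) return(0)
    delta <- (vm - vp) / (2 * den)
    if (abs(delta) > 0.5) return(0)
    delta
  }
  dx <- 0
  if (x >= 1 && x <= c - 2) {
    dx <- refine_axis(part_map[y + 1, x], part_map[y + 1, x + 1], part_map[y + 1, x + 2])
  }
  dy <- 0
  if (y >= 1 && y <= r - 2) {
    dy <- refine_axis(part_map[y, x + 1], part_map[y + 1, x + 1], part_map[y + 2, x + 1])
  }
  c(x + dx, y + dy)
}

# bilinear sample of one channel at real-valued (x, y), clamped to bounds
bilinear_sample <- function(map, x, y) {
  r <- nrow(map); c <- ncol(map)
  x <- min(max(x, 0), c - 1)
  y <- min(max(y, 0), r - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, c - 1); y1 <- min(y0 + 1, r - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- map[y0 + 1, x0 + 1]; v01 <- map[y0 + 1, x1 + 1]
  v10 <- map[y1 + 1, x0 + 1]; v11 <- map[y1 + 1, x1 + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Estimate an associated part location from the vector channels
#'
#' Bilinearly samples the (x, y) association channel pair for direction
#' `from -> to` at a (possibly sub-pixel) source location and returns
#' `source - offset`, the estimated partner location: the channels store
#' `from - to`, so subtracting the sampled offset lands on the partner.
#'
#' @param assoc_maps `[R, C, 12]` association channel array.
#' @param source numeric `c(x, y)` location of the source part.
#' @param from,to part names selecting the channel pair.
#' @return numeric `c(x, y)` estimated partner location.
#' @export
sample_association <- function(assoc_maps, source, from, to) {
  pair <- assoc_pair(from, to)
  off_x <- bilinear_sample(assoc_maps[, , pair[1]], source[1], source[2])
  off_y <- bilinear_sample(assoc_maps[, , pair[2]], source[1], source[2])
  c(source[1] - off_x, source[2] - off_y)
}

#' Symmetric association distance between two detected parts
#'
#' The association distance between part `p` and candidate partner `q` is
#' the mean of the two prediction errors: how far `p`'s predicted partner
#' lands from `q`, and how far `q`'s predicted partner lands from `p`.
#'
#' @param p,q numeric `c(x, y)` detected part locations.
#' @param p_to_q predicted partner of `p` (from [sample_association()]).
#' @param q_to_p predicted partner of `q`.
#' @return Non-negative scalar.
#' @export
association_distance <- function(p, p_to_q, q, q_to_p) {
  (euclidean_norm(p_to_q, q) + euclidean_norm(q_to_p, p)) / 2
}

#' Pairwise part-to-part distance matrix
#'
#' Builds the `Np x Nq` cost matrix between two sets of detected parts for
#' one of the three grouped pairs (left ear/shoulder, right ear/shoulder,
#' shoulder/tail). In `"vector"` mode entries are association distances; in
#' `"euclidean"` mode they are plain Euclidean distances (the ablation
#' baseline).
#'
#' @param parts_p,parts_q matrices with columns `x`, `y` (and optionally
#'   `value`) as returned by [detect_peaks()]; may have zero rows.
#' @param assoc_maps `[R, C, 12]` association array (ignored in euclidean
#'   mode).
#' @param from,to part names of `parts_p` and `parts_q`.
#' @param mode `"vector"` or `"euclidean"`.
#' @return Numeric `Np x Nq` matrix (possibly with a zero dimension).
#' @export
build_distance_matrix <- function(parts_p, parts_q, assoc_maps, from, to,
                                  mode = c("vector", "euclidean")) {
  mode <- match.arg(mode)
  np <- nrow(parts_p); nq <- nrow(parts_q)
  D <- matrix(0, np, nq)
  if (np == 0 || nq == 0) return(D)
  if (mode == "euclidean") {
    for (n in seq_len(np)) for (m in seq_len(nq)) {
      D[n, m] <- euclidean_norm(parts_p[n, c("x", "y")], parts_q[m, c("x", "y")])
    }
    return(D)
  }
  fwd <- t(vapply(seq_len(np), function(n) {
    sample_association(assoc_maps, parts_p[n, c("x", "y")], from, to)
  }, numeric(2)))
  bwd <- t(vapply(seq_len(nq), function(m) {
    sample_association(assoc_maps, parts_q[m, c("x", "y")], to, from)
  }, numeric(2)))
  for (n in seq_len(np)) {
    for (m in seq_len(nq)) {
      D[n, m] <- association_distance(
        p = parts_p[n, c("x", "y")], p_to_q = fwd[n, ],
        q = parts_q[m, c("x", "y")], q_to_p = bwd[m, ]
      )
    }
  }
  D
}

#' Detected instances for one frame
#'
#' A detection set is a tibble with one row per detected animal: shoulder
#' and tail coordinates (always present; an instance is a joined
#' shoulder-tail pair), optional ear coordinates, and a confidence equal to
#' the minimum peak heatmap value among the constituent parts.
#'
#' @param detections data frame with the coordinate columns of
#'   [frame_annotation()] plus `confidence`.
#' @param image_size integer `c(rows, cols)`.
#' @return Tibble of class `detection_set`.
#' @export
detection_set <- function(detections = NULL, image_size) {
  cols <- c(
    "instance_id", "shoulder_x", "shoulder_y", "tail_x", "tail_y",
    "left_ear_x", "left_ear_y", "right_ear_x", "right_ear_y", "confidence"
  )
  if (is.null(detections) || nrow(detections) == 0) {
    detections <- tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(numeric(0)), 9)), cols
    ))
  } else {
    detections <- tibble::as_tibble(detections)
    if (!"instance_id" %in% names(detections)) {
      detections$instance_id <- seq_len(nrow(detections))
    }
    for (nm in setdiff(cols, names(detections))) detections[[nm]] <- NA_real_
    detections <- detections[cols]
  }
  tibble::new_tibble(detections, image_size = as.integer(image_size),
                     class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  size <- attr(x, "image_size", exact = TRUE)
  cat(sprintf("<detection_set> %d instance(s), image %d x %d\n",
              nrow(x), size[1], size[2]))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Form whole-animal instances from part assignments
#'
#' Instances are the matched shoulder-tail pairs; each ear is then attached
#' to its assigned shoulder only when that shoulder belongs to a formed
#' instance (ear assignments to instance-less shoulders are dropped), and
#' unmatched parts are discarded. Confidence is the minimum peak value over
#' the instance's parts.
#'
#' @param parts named list of peak matrices (one per part type) from
#'   [detect_peaks()].
#' @param st_assign,ls_assign,rs_assign assignment matrices from
#'   [hungarian_assign()] for shoulder/tail, left-ear/shoulder and
#'   right-ear/shoulder.
#' @param image_size integer `c(rows, cols)`.
#' @return A [detection_set()].
#' @export
form_instances <- function(parts, st_assign, ls_assign, rs_assign, image_size) {
  if (nrow(st_assign) == 0) return(detection_set(NULL, image_size))
  sh <- parts$shoulder; tl <- parts$tail
  le <- parts$left_ear; re <- parts$right_ear
  # shoulder index -> instance row
  inst <- tibble::tibble(
    shoulder_idx = st_assign[, "row"],
    shoulder_x = sh[st_assign[, "row"], "x"],
    shoulder_y = sh[st_assign[, "row"], "y"],
    tail_x = tl[st_assign[, "col"], "x"],
    tail_y = tl[st_assign[, "col"], "y"],
    left_ear_x = NA_real_, left_ear_y = NA_real_,
    right_ear_x = NA_real_, right_ear_y = NA_real_,
    confidence = pmin(sh[st_assign[, "row"], "value"],
                      tl[st_assign[, "col"], "value"])
  )
  attach_ear <- function(inst, ear_parts, assign, prefix) {
    if (nrow(assign) == 0) return(inst)
    for (k in seq_len(nrow(assign))) {
      i <- match(assign[k, "col"], inst$shoulder_idx)
      if (is.na(i)) next # ear assigned to a shoulder that formed no instance
      inst[[paste0(prefix, "_x")]][i] <- ear_parts[assign[k, "row"], "x"]
      inst[[paste0(prefix, "_y")]][i] <- ear_parts[assign[k, "row"], "y"]
      inst$confidence[i] <- min(inst$confidence[i], ear_parts[assign[k, "row"], "value"])
    }
    inst
  }
  inst <- attach_ear(inst, le, ls_assign, "left_ear")
  inst <- attach_ear(inst, re, rs_assign, "right_ear")
  inst$shoulder_idx <- NULL
  inst$instance_id <- seq_len(nrow(inst))
  detection_set(inst, image_size)
}

#' Decode a 16-channel map into detected instances
#'
#' Full pipeline: smooth all channels with the box filter, detect regional
#' maxima per part channel, refine peaks to sub-pixel accuracy, build the
#' three part-pair distance matrices (association-vector or Euclidean),
#' solve each with the Hungarian algorithm and assemble shoulder-tail
#' instances with attached ears.
#'
#' @param maps a `target_maps` object or `[R, C, 16]` array (e.g. a network
#'   output).
#' @param config a [decoder_config()].
#' @param verbose log per-stage counts (parts detected per type, distance
#'   matrix sizes, matches) via [message()] -- useful when diagnosing why a
#'   frame decodes to fewer instances than expected.
#' @return A [detection_set()].
#' @export
#' @examples
#' fr <- frame_annotation(
#'   tibble::tibble(shoulder_x = 60, shoulder_y = 40, tail_x = 120, tail_y = 44),
#'   image_size = c(96, 160)
#' )
#' decode_maps(encode_frame(fr))
decode_maps <- function(maps, config = decoder_config(), verbose = FALSE) {
  maps <- as_target_maps(maps)
  size <- maps$image_size
  maps <- smooth_maps(maps, config$smooth_kernel)
  parts <- list()
  for (part in part_types()) {
    ch <- part_channel(part)
    pm <- maps$part[, , ch]
    pk <- detect_peaks(pm, config)
    if (nrow(pk) > 0) {
      refined <- t(vapply(seq_len(nrow(pk)), function(i) {
        subpixel_refine(pm, c(pk[i, "x"], pk[i, "y"]))
      }, numeric(2)))
      pk[, "x"] <- refined[, 1]
      pk[, "y"] <- refined[, 2]
    }
    parts[[part]] <- pk
  }
  if (verbose) {
    message("parts detected: ",
            paste(sprintf("%s=%d", part_types(),
                          vapply(parts, nrow, 0L)), collapse = ", "))
  }
  mode <- config$association_mode
  D_st <- build_distance_matrix(parts$shoulder, parts$tail, maps$assoc,
                                "shoulder", "tail", mode)
  D_ls <- build_distance_matrix(parts$left_ear, parts$shoulder, maps$assoc,
                                "left_ear", "shoulder", mode)
  D_rs <- build_distance_matrix(parts$right_ear, parts$shoulder, maps$assoc,
                                "right_ear", "shoulder", mode)
  gate <- function(assign, D) {
    if (!is.finite(config$max_assignment_distance) || nrow(assign) == 0) {
      return(assign)
    }
    assign[D[assign] <= config$max_assignment_distance, , drop = FALSE]
  }
  st <- gate(hungarian_assign(D_st), D_st)
  ls <- gate(hungarian_assign(D_ls), D_ls)
  rs <- gate(hungarian_assign(D_rs), D_rs)
  if (verbose) {
    message(sprintf(
      "distance matrices: s-t %dx%d, l-s %dx%d, r-s %dx%d; matched %d shoulder-tail pair(s)",
      nrow(D_st), ncol(D_st), nrow(D_ls), ncol(D_ls),
      nrow(D_rs), ncol(D_rs), nrow(st)
    ))
  }
  form_instances(parts, st_assign = st, ls_assign = ls, rs_assign = rs,
                 image_size = size)
}
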