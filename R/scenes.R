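#' Synthetic top-down pen scene configuration
#'
#' The generator emulates the geometry of top-down pen images: elongated,
#' bilaterally symmetric bodies (filled ellipses with a brighter head disc)
#' on a textured floor, optionally abutting side-by-side in close pairs, with
#' an optional polygonal pen mask blacking out out-of-pen pixels. Keypoints
#' are placed deterministically from each body's pose: the tail at the rear
#' end of the major axis, the shoulder 70% along the major axis from the
#' tail, and the ears flanking the head at a perpendicular offset of
#' 0.25 x body length. Appearance is deliberately simple -- correctness of
#' encoding, decoding and matching does not depend on photo-realism.
#'
#' @param image_size integer `c(rows, cols)`; default 360 x 480 (the
#'   480-column working scale).
#' @param n_pigs integer range `c(min, max)` of instances per scene.
#' @param length_range shoulder-to-tail distance range in pixels at the
#'   configured scale; default 30-140, the span observed at 480 columns
#'   (the rendered body extends past the shoulder to the snout).
#' @param abutting_fraction fraction of instances placed as close
#'   side-by-side pairs (gap under 0.3 x body width).
#' @param width_ratio body width as a fraction of body length.
#' @param texture background texture amplitude.
#' @param noise_sigma additive Gaussian pixel noise standard deviation.
#' @param mask optional two-column (x, y) polygon; pixels outside are black
#'   and keypoints are constrained inside.
#' @param min_separation optional minimum distance between same-type
#'   keypoints of different instances (used by round-trip suites to keep
#'   kernels from interfering); `NULL` disables the constraint.
#' @param border_margin minimum distance of annotated keypoints from the
#'   image border, pixels. Round-trip suites raise it so part kernels are
#'   never truncated by the frame edge, where box filtering with replicate
#'   padding biases peak localisation.
#' @param max_retries placement attempts per instance before the scene is
#'   declared infeasible.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = c(360L, 480L),
                         n_pigs = c(2L, 12L),
                         length_range = c(30, 140),
                         abutting_fraction = 0.25,
                         width_ratio = 0.36,
                         texture = 0.08,
                         noise_sigma = 0.02,
                         mask = NULL,
                         min_separation = NULL,
                         border_margin = 1,
                         max_retries = 200L) {
  stopifnot(length(image_size) == 2, all(image_size > 0),
            length(n_pigs) == 2, n_pigs[1] >= 0, n_pigs[2] >= n_pigs[1],
            length_range[1] > 0, length_range[2] >= length_range[1],
            abutting_fraction >= 0, abutting_fraction <= 1)
  structure(
    list(image_size = as.integer(image_size), n_pigs = as.integer(n_pigs),
         length_range = length_range, abutting_fraction = abutting_fraction,
         width_ratio = width_ratio, texture = texture,
         noise_sigma = noise_sigma, mask = mask,
         min_separation = min_separation, border_margin = border_margin,
         max_retries = as.integer(max_retries)),
    class = "scene_config"
  )
}

# keypoints of a body from (tail position, unit direction, length)
body_keypoints <- function(tail, u, len) {
  perp <- c(-u[2], u[1])
  list(
    tail = tail,
    shoulder = tail + u * 0.7 * len,
    left_ear = tail + u * 0.9 * len + perp * 0.25 * len,
    right_ear = tail + u * 0.9 * len - perp * 0.25 * len
  )
}

# note: with y pointing down, perp = (-uy, ux) is the animal's left side
# when the animal faces along u.

point_in_image <- function(pt, size, margin = 1) {
  pt[1] >= margin && pt[1] < size[2] - margin && pt[2] >= margin && pt[2] < size[1] - margin
}

point_in_mask <- function(pt, mask) {
  if (is.null(mask)) return(TRUE)
  pracma::inpolygon(pt[1], pt[2], mask[, 1], mask[, 2])
}

#' Generate one synthetic scene
#'
#' A pure function of `(config, seed)`: the same pair always yields a
#' bit-identical image and annotation.
#'
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return List with `image` (array `[R, C, 3]` in `[0, 1]`) and `frame`
#'   (a [frame_annotation()]).
#' @export
#' @examples
#' sc <- generate_scene(scene_config(image_size = c(96, 128), n_pigs = c(2, 3),
#'                                   length_range = c(20, 35)), seed = 1)
#' nrow(sc$frame)
generate_scene <- function(config, seed) {
  withr::with_seed(as.integer(seed), generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  size <- config$image_size
  n <- if (config$n_pigs[1] == config$n_pigs[2]) config$n_pigs[1] else
    sample(config$n_pigs[1]:config$n_pigs[2], 1)
  pigs <- list()
  placed_kp <- list()
  n_pairs <- floor(config$abutting_fraction * n / 2)
  plan <- c(rep("pair", n_pairs), rep("single", n - 2 * n_pairs))

  sep_ok <- function(kp) {
    if (is.null(config$min_separation)) return(TRUE)
    for (old in placed_kp) {
      for (part in c("tail", "shoulder", "left_ear", "right_ear")) {
        if (euclidean_norm(kp[[part]], old[[part]]) < config$min_separation) return(FALSE)
      }
    }
    TRUE
  }
  body_ok <- function(tail, u, len, partner_of = NULL) {
    kp <- body_keypoints(tail, u, len)
    m <- config$border_margin
    core_in <- point_in_image(kp$tail, size, m) && point_in_image(kp$shoulder, size, m) &&
      point_in_mask(kp$tail, config$mask) && point_in_mask(kp$shoulder, config$mask)
    if (!core_in) return(NULL)
    if (!sep_ok(kp)) return(NULL)
    # keep distinct bodies from lying on top of each other
    ctr <- tail + u * len / 2
    for (i in seq_along(pigs)) {
      if (!is.null(partner_of) && i == partner_of) next
      p <- pigs[[i]]
      min_gap <- 0.55 * (len * config$width_ratio + p$len * p$width_ratio) +
        0.25 * (len + p$len)
      if (euclidean_norm(ctr, p$tail + p$u * p$len / 2) < min_gap) return(NULL)
    }
    kp
  }

  for (item in plan) {
    placed <- FALSE
    for (try in seq_len(config$max_retries)) {
      # length_range governs the shoulder-to-tail distance; the full body
      # (tail to snout) extends to delta / 0.7 since the shoulder sits at
      # 70% of the major axis
      len <- stats::runif(1, config$length_range[1], config$length_range[2]) / 0.7
      th <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(th), sin(th))
      tail <- c(stats::runif(1, 0, size[2] - 1), stats::runif(1, 0, size[1] - 1))
      kp <- body_ok(tail, u, len)
      if (is.null(kp)) next
      if (item == "single") {
        pigs[[length(pigs) + 1L]] <- list(tail = tail, u = u, len = len,
                                          width_ratio = config$width_ratio)
        placed_kp[[length(placed_kp) + 1L]] <- kp
        placed <- TRUE
        break
      }
      # abutting partner: parallel, side by side, touching (slight squeeze)
      len2 <- len * stats::runif(1, 0.95, 1.05)
      perp <- c(-u[2], u[1])
      offset <- perp * config$width_ratio * len * stats::runif(1, 0.75, 0.9)
      u2 <- u
      tail2 <- tail + u * len * stats::runif(1, -0.05, 0.05) + offset
      kp2 <- body_ok(tail2, u2, len2, partner_of = length(pigs) + 1L)
      if (is.null(kp2)) next
      pigs[[length(pigs) + 1L]] <- list(tail = tail, u = u, len = len,
                                        width_ratio = config$width_ratio)
      placed_kp[[length(placed_kp) + 1L]] <- kp
      pigs[[length(pigs) + 1L]] <- list(tail = tail2, u = u2, len = len2,
                                        width_ratio = config$width_ratio)
      placed_kp[[length(placed_kp) + 1L]] <- kp2
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: could not place ", n, " pigs after retries")
  }

  frame <- frame_from_bodies(placed_kp, size, config$mask, config$border_margin)
  image <- render_bodies(pigs, config)
  list(image = image, frame = frame)
}

# assemble a frame_annotation, dropping ears that leave image or mask
frame_from_bodies <- function(kps, size, mask, margin = 1) {
  if (length(kps) == 0) return(frame_annotation(NULL, size, mask))
  rows <- purrr::imap(kps, function(kp, i) {
    ear <- function(pt) {
      if (point_in_image(pt, size, margin) && point_in_mask(pt, mask)) {
        pt
      } else {
        c(NA_real_, NA_real_)
      }
    }
    le <- ear(kp$left_ear); re <- ear(kp$right_ear)
    tibble::tibble(
      instance_id = i,
      shoulder_x = kp$shoulder[1], shoulder_y = kp$shoulder[2],
      tail_x = kp$tail[1], tail_y = kp$tail[2],
      left_ear_x = le[1], left_ear_y = le[2],
      right_ear_x = re[1], right_ear_y = re[2]
    )
  })
  frame_annotation(dplyr::bind_rows(rows), size, mask)
}

# render filled elliptical bodies + head discs + texture + noise (+ mask)
render_bodies <- function(pigs, config) {
  size <- config$image_size
  r <- size[1]; c <- size[2]
  # coarse smooth texture: random low-res grid, bilinearly upsampled
  gr <- max(2L, r %/% 24L); gc <- max(2L, c %/% 24L)
  coarse <- matrix(stats::runif(gr * gc, -1, 1), gr, gc)
  yi <- seq(1, gr, length.out = r); xi <- seq(1, gc, length.out = c)
  y0 <- pmin(floor(yi), gr - 1L); x0 <- pmin(floor(xi), gc - 1L)
  fy <- yi - y0; fx <- xi - x0
  tex <- matrix(0, r, c)
  for (ix in seq_len(c)) {
    cx0 <- x0[ix]; fxx <- fx[ix]
    col <- (1 - fy) * ((1 - fxx) * coarse[y0, cx0] + fxx * coarse[y0, cx0 + 1L]) +
      fy * ((1 - fxx) * coarse[y0 + 1L, cx0] + fxx * coarse[y0 + 1L, cx0 + 1L])
    tex[, ix] <- col
  }
  base <- 0.18 + config$texture * tex
  img <- base
  xs <- matrix(rep(0:(c - 1), each = r), r, c)
  ys <- matrix(rep(0:(r - 1), times = c), r, c)
  for (p in pigs) {
    ctr <- p$tail + p$u * p$len / 2
    h <- p$len / 2
    hw <- p$len * p$width_ratio / 2
    dx <- xs - ctr[1]; dy <- ys - ctr[2]
    ax <- dx * p$u[1] + dy * p$u[2]
    px <- -dx * p$u[2] + dy * p$u[1]
    body <- (ax / h)^2 + (px / hw)^2 <= 1
    shade <- 0.5 + stats::runif(1, -0.08, 0.08)
    img[body] <- shade + 0.1 * (1 - (abs(px[body]) / hw))
    # brighter head disc at the front end
    hctr <- p$tail + p$u * p$len * 0.85
    hr <- 0.16 * p$len
    head <- (xs - hctr[1])^2 + (ys - hctr[2])^2 <= hr^2
    img[head] <- shade + 0.28
    # small ear nubs
    kp <- body_keypoints(p$tail, p$u, p$len)
    for (e in list(kp$left_ear, kp$right_ear)) {
      er <- 0.05 * p$len
      ear <- (xs - e[1])^2 + (ys - e[2])^2 <= er^2
      img[ear] <- shade + 0.18
    }
  }
  img <- img + matrix(stats::rnorm(r * c, 0, config$noise_sigma), r, c)
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(config$mask)) {
    inside <- matrix(
      pracma::inpolygon(as.vector(xs), as.vector(ys),
                        config$mask[, 1], config$mask[, 2]),
      r, c
    )
    img[!inside] <- 0
  }
  out <- array(0, c(r, c, 3L))
  out[, , 1] <- img
  out[, , 2] <- pmin(img * 0.97 + 0.01, 1)
  out[, , 3] <- pmin(img * 0.93 + 0.02, 1)
  out
}

#' Abutting-pig ablation suite
#'
#' Close-proximity configurations for comparing association-vector grouping
#' against the Euclidean-distance baseline. `pair` is an anti-parallel
#' side-by-side pair whose shoulders sit next to the neighbour's tail, so
#' nearest-neighbour grouping swaps the tails; `pinwheel` is four pigs
#' laid head-to-tail around a square, where Euclidean grouping commits a
#' four-way cyclic cross-pairing whose spurious instances fail the
#' mutual-minimum evaluation check (precision drops), while vector grouping
#' recovers every animal.
#'
#' @param seed integer seed (rendering noise only; keypoints are fixed).
#' @return Named list of scenes (`image`, `frame`).
#' @export
abutting_suite <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    size <- c(240L, 320L)
    cfg <- scene_config(image_size = size, texture = 0.05, noise_sigma = 0.01)
    from_keypoints <- function(kp_list) {
      # reconstruct body pose from shoulder/tail (shoulder at 70% of length)
      pigs <- purrr::map(kp_list, function(kp) {
        v <- kp$s - kp$t
        len <- sqrt(sum(v^2)) / 0.7
        list(tail = kp$t, u = v / sqrt(sum(v^2)), len = len,
             width_ratio = cfg$width_ratio)
      })
      kps <- purrr::map(pigs, function(b) body_keypoints(b$tail, b$u, b$len))
      # keep the annotated shoulder/tail exactly as specified
      kps <- purrr::map2(kps, kp_list, function(k, kp) {
        k$tail <- kp$t; k$shoulder <- kp$s; k
      })
      list(image = render_bodies(pigs, cfg),
           frame = frame_from_bodies(kps, size, NULL))
    }
    list(
      pair = from_keypoints(list(
        list(t = c(60, 100), s = c(120.2, 100)),
        list(t = c(126, 124), s = c(65.8, 124))
      )),
      pinwheel = from_keypoints(list(
        list(s = c(160.4, 60.8), t = c(70.8, 57.9)),
        list(s = c(171.2, 137.3), t = c(162.5, 74.5)),
        list(s = c(87.4, 158.8), t = c(160.5, 158.3)),
        list(s = c(57.7, 70.6), t = c(62.9, 136.3))
      ))
    )
  })
}

#' Deterministic fixture suite
#'
#' Six named scenes covering the regimes the decoder must handle: a single
#' pig; an anti-parallel abutting pair whose shoulders sit next to the
#' neighbour's tail (the regime where plain Euclidean grouping cross-pairs);
#' a head-to-tail chain; a pig at the pen-mask border whose ears fall
#' outside the mask and are dropped; a dense 12-pig pen; and an empty pen.
#'
#' @param seed integer seed (controls rendering noise and the dense-pen
#'   layout only; keypoint geometry of the constructed fixtures is fixed).
#' @return Named list of scenes, each a list with `image` and `frame`.
#' @export
generate_fixture_suite <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    size <- c(240L, 320L)
    cfg <- scene_config(image_size = size, texture = 0.05, noise_sigma = 0.01)
    mk <- function(bodies, mask = NULL) {
      kps <- purrr::map(bodies, function(b) body_keypoints(b$tail, b$u, b$len))
      pigs <- purrr::map(bodies, function(b) {
        list(tail = b$tail, u = b$u, len = b$len, width_ratio = cfg$width_ratio)
      })
      cfg2 <- cfg; cfg2$mask <- mask
      list(image = render_bodies(pigs, cfg2),
           frame = frame_from_bodies(kps, size, mask))
    }
    ux <- c(1, 0)
    list(
      single = mk(list(list(tail = c(100, 120), u = ux, len = 80))),
      abutting_pair = mk(list(
        list(tail = c(60, 100), u = ux, len = 86),
        list(tail = c(126, 124), u = -ux, len = 86)
      )),
      chain = mk(list(
        list(tail = c(20, 60), u = ux, len = 60),
        list(tail = c(120, 60), u = ux, len = 60),
        list(tail = c(220, 60), u = ux, len = 60)
      )),
      masked_border = mk(
        list(list(tail = c(150, 150), u = c(0, 1), len = 62)),
        mask = cbind(c(10, 310, 310, 10), c(10, 10, 200, 200))
      ),
      dense_pen = generate_scene_impl(scene_config(
        image_size = c(360L, 480L), n_pigs = c(12L, 12L),
        length_range = c(40, 60), abutting_fraction = 0,
        min_separation = 2 * 0.16 * 2 * 60, texture = 0.05, noise_sigma = 0.01
      )),
      empty = mk(list())
    )
  })
}
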