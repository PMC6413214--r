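# shared fixtures and independent oracles

make_pig <- function(sx, sy, tx, ty, lx = NA_real_, ly = NA_real_,
                     rx = NA_real_, ry = NA_real_, id = 1L) {
  tibble::tibble(
    instance_id = id,
    shoulder_x = sx, shoulder_y = sy, tail_x = tx, tail_y = ty,
    left_ear_x = lx, left_ear_y = ly, right_ear_x = rx, right_ear_y = ry
  )
}

one_pig_frame <- function(size = c(240, 320)) {
  frame_annotation(make_pig(50, 40, 150, 40), image_size = size)
}

# random well-separated frame for round-trip checks: same-type keypoints of
# distinct pigs are at least 2 * max(sigma) apart
random_separated_frame <- function(seed, n_range = c(2, 12),
                                   size = c(360, 480), len_range = c(30, 80)) {
  cfg <- scene_config(
    image_size = size, n_pigs = n_range, length_range = len_range,
    abutting_fraction = 0,
    min_separation = 2 * 0.16 * 2 * len_range[2],
    border_margin = 8
  )
  generate_scene(cfg, seed = seed)$frame
}

# exhaustive-permutation assignment oracle (minimum total cost)
brute_force_assign <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(list(cost = 0, pairs = NULL))
  transposed <- nr > nc
  if (transposed) { cost <- t(cost); tmp <- nr; nr <- nc; nc <- tmp }
  perms <- gtools_permutations(nc, nr)
  best <- Inf; best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    tot <- sum(cost[cbind(seq_len(nr), perms[i, ])])
    if (tot < best) { best <- tot; best_perm <- perms[i, ] }
  }
  pairs <- cbind(row = seq_len(nr), col = best_perm)
  if (transposed) pairs <- cbind(row = pairs[, "col"], col = pairs[, "row"])
  list(cost = best, pairs = pairs)
}

# all k-permutations of 1:n (small n only)
gtools_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- gtools_permutations(n - 1, k - 1)
    rest <- matrix(setdiff(seq_len(n), i)[rest], nrow = nrow(rest))
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# brute-force regional maximum scan matching the decoder definition
brute_force_peaks <- function(map, window, threshold) {
  p <- window %/% 2
  r <- nrow(map); c <- ncol(map)
  hits <- NULL
  for (y in 0:(r - 1)) {
    for (x in 0:(c - 1)) {
      v <- map[y + 1, x + 1]
      if (v < threshold) next
      nb <- map[max(1, y + 1 - p):min(r, y + 1 + p),
                max(1, x + 1 - p):min(c, x + 1 + p)]
      if (v >= max(nb)) hits <- rbind(hits, c(x = x, y = y))
    }
  }
  hits
}
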