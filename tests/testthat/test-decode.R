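test_that("box filter preserves constants and affine ramps, spreads impulses", {
  k <- 5
  const <- matrix(3.7, 20, 30)
  expect_equal(pigparts:::box_filter(const, k), const)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- pigparts:::box_filter(imp, k)
  expect_equal(sm[9:13, 9:13], matrix(1 / 25, 5, 5))
  expect_equal(sum(sm), 1)
  ramp <- outer(1:30, 1:40, function(i, j) 2 * i + 3 * j)
  smr <- pigparts:::box_filter(ramp, k)
  expect_equal(smr[5:26, 5:36], ramp[5:26, 5:36])
})

test_that("regional maxima match an exhaustive neighbourhood scan", {
  cfg <- decoder_config(detection_threshold = 0.25)
  expect_equal(nrow(detect_peaks(matrix(0, 50, 50), cfg)), 0)
  # single kernel
  g <- outer(0:79, 0:99, function(y, x) exp(-((x - 60)^2 + (y - 40)^2) / (2 * 36)))
  pk <- detect_peaks(g, cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(unname(pk[1, c("x", "y")]), c(60, 40))
  # two kernels 30 px apart -> two peaks
  g2 <- pmax(g, outer(0:79, 0:99, function(y, x)
    exp(-((x - 30)^2 + (y - 40)^2) / (2 * 36))))
  expect_equal(nrow(detect_peaks(g2, cfg)), 2)
  # randomized smooth maps against the brute-force oracle
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(stats::runif(30 * 40), 30, 40)
    m <- pigparts:::box_filter(m, 7)
    got <- detect_peaks(m, decoder_config(detection_threshold = 0.4, peak_window = 9))
    want <- brute_force_peaks(m, 9, 0.4)
    nw <- if (is.null(want)) 0 else nrow(want)
    expect_equal(nrow(got), nw)
    if (nw > 0) {
      expect_setequal(paste(got[, "x"], got[, "y"]), paste(want[, "x"], want[, "y"]))
    }
  }
})

test_that("tied plateaus yield a single detection at the smallest (y, x)", {
  m <- matrix(0, 40, 40)
  m[20:22, 20:22] <- 0.9 # 3x3 plateau
  pk <- detect_peaks(m, decoder_config(detection_threshold = 0.25))
  expect_equal(nrow(pk), 1)
  expect_equal(unname(pk[1, c("x", "y")]), c(19, 19))
})

test_that("quadratic sub-pixel refinement hits the parabola vertex with guards", {
  m <- matrix(0, 9, 9)
  # symmetric neighbours: no shift
  m[5, 4:6] <- c(0.8, 1, 0.8); m[4, 5] <- 0.8; m[6, 5] <- 0.8
  expect_equal(subpixel_refine(m, c(4, 4)), c(4, 4))
  # samples (0.5, 1.0, 0.9) -> delta = 1/3 on x
  m2 <- matrix(0, 9, 9)
  m2[5, 4:6] <- c(0.5, 1, 0.9); m2[4, 5] <- 1; m2[6, 5] <- 1 # flat in y: denom >= 0, no y shift
  ref <- subpixel_refine(m2, c(4, 4))
  expect_equal(ref[1], 4 + 1 / 3, tolerance = 1e-12)
  expect_equal(ref[2], 4)
  # peak on the border stays unrefined
  m3 <- matrix(0, 9, 9); m3[1, 1] <- 1
  expect_equal(subpixel_refine(m3, c(0, 0)), c(0, 0))
})

test_that("association sampling inverts the stored offsets bilinearly", {
  assoc <- array(0, c(100, 100, 12))
  st <- assoc_channels(); st <- st[st$from == "shoulder" & st$to == "tail", ]
  assoc[, , st$x_channel] <- -30
  est <- sample_association(assoc, c(50, 50), "shoulder", "tail")
  expect_equal(est, c(80, 50))
  # zero offsets: estimate equals source
  est0 <- sample_association(array(0, c(100, 100, 12)), c(33.5, 41.2),
                             "left_ear", "shoulder")
  expect_equal(est0, c(33.5, 41.2))
  # bilinear midpoint between column values 10 and 20
  a2 <- array(0, c(50, 50, 12))
  a2[, 1:11, st$x_channel] <- 10
  a2[, 12:50, st$x_channel] <- 20
  est2 <- sample_association(a2, c(10.5, 25), "shoulder", "tail")
  expect_equal(est2[1], 10.5 - 15)
})

test_that("association distance averages forward and backward errors", {
  expect_equal(association_distance(c(0, 0), c(10, 0), c(10, 0), c(0, 0)), 0)
  # forward error 4, backward error 2 -> 3
  expect_equal(association_distance(c(0, 0), c(10, 4), c(10, 0), c(2, 0)), 3)
  # symmetric under role swap
  set.seed(2)
  for (i in 1:5) {
    p <- stats::runif(2, 0, 50); q <- stats::runif(2, 0, 50)
    pq <- stats::runif(2, 0, 50); qp <- stats::runif(2, 0, 50)
    expect_equal(association_distance(p, pq, q, qp),
                 association_distance(q, qp, p, pq))
  }
})

test_that("distance matrices match a scalar recomputation and handle empties", {
  fr <- frame_annotation(make_pig(60, 40, 120, 44), image_size = c(96, 160))
  enc <- encode_frame(fr)
  sh <- cbind(x = 60, y = 40, value = 1)
  tl <- cbind(x = 120, y = 44, value = 1)
  D <- build_distance_matrix(sh, tl, enc$assoc, "shoulder", "tail", "vector")
  expect_equal(dim(D), c(1, 1))
  expect_equal(D[1, 1], 0, tolerance = 1e-9)
  D0 <- build_distance_matrix(sh[0, , drop = FALSE], tl, enc$assoc,
                              "shoulder", "tail", "vector")
  expect_equal(dim(D0), c(0, 1))
  expect_equal(nrow(hungarian_assign(D0)), 0)
  # random 3x4 euclidean configuration vs scalar oracle
  set.seed(9)
  p <- cbind(x = stats::runif(3, 0, 90), y = stats::runif(3, 0, 90), value = 1)
  q <- cbind(x = stats::runif(4, 0, 90), y = stats::runif(4, 0, 90), value = 1)
  De <- build_distance_matrix(p, q, enc$assoc, "shoulder", "tail", "euclidean")
  for (n in 1:3) for (m in 1:4) {
    expect_equal(De[n, m], euclidean_norm(p[n, 1:2], q[m, 1:2]))
  }
})

test_that("hungarian assignment equals the exhaustive permutation optimum", {
  expect_equal(hungarian_assign(rbind(c(1, 10), c(10, 1))),
               cbind(row = 1:2, col = 1:2))
  expect_equal(hungarian_assign(matrix(7, 1, 1)), cbind(row = 1L, col = 1L))
  set.seed(6)
  for (i in 1:150) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    D <- matrix(stats::runif(nr * nc, 0, 100), nr, nc)
    got <- hungarian_assign(D)
    expect_equal(nrow(got), min(nr, nc))
    got_cost <- sum(D[got])
    expect_equal(got_cost, brute_force_assign(D)$cost, tolerance = 1e-9)
  }
})

test_that("instances are joined shoulder-tail pairs with ears attached afterwards", {
  sh <- cbind(x = c(20, 90), y = c(10, 10), value = c(0.9, 0.8))
  tl <- cbind(x = c(30, 100), y = c(30, 30), value = c(0.95, 0.7))
  st <- cbind(row = 1:2, col = 1:2)
  empty <- cbind(row = integer(0), col = integer(0))
  parts <- list(shoulder = sh, tail = tl,
                left_ear = sh[0, , drop = FALSE], right_ear = sh[0, , drop = FALSE])
  ds <- form_instances(parts, st, empty, empty, c(64, 128))
  expect_equal(nrow(ds), 2)
  expect_equal(ds$confidence, c(0.9, 0.7))
  # a lone shoulder with no tails forms nothing
  parts1 <- list(shoulder = sh[1, , drop = FALSE], tail = tl[0, , drop = FALSE],
                 left_ear = sh[0, , drop = FALSE], right_ear = sh[0, , drop = FALSE])
  ds1 <- form_instances(parts1, empty, empty, empty, c(64, 128))
  expect_equal(nrow(ds1), 0)
  # ear assigned to an instance-less shoulder is dropped
  le <- cbind(x = 15, y = 5, value = 0.6)
  st_one <- cbind(row = 1L, col = 1L) # only shoulder 1 forms an instance
  ls_to_lone <- cbind(row = 1L, col = 2L) # ear joined to shoulder 2
  parts2 <- list(shoulder = sh, tail = tl[1, , drop = FALSE],
                 left_ear = le, right_ear = sh[0, , drop = FALSE])
  ds2 <- form_instances(parts2, st_one, ls_to_lone, empty, c(64, 128))
  expect_equal(nrow(ds2), 1)
  expect_true(is.na(ds2$left_ear_x))
})

test_that("decoding is threshold-monotone and translation-equivariant", {
  enc0 <- encode_frame(frame_annotation(NULL, c(64, 64)))
  expect_equal(nrow(decode_maps(enc0)), 0)
  fr <- random_separated_frame(77, n_range = c(4, 4), size = c(240, 320),
                               len_range = c(30, 50))
  enc <- encode_frame(fr)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.9, 0.98), function(th) {
    nrow(decode_maps(enc, decoder_config(detection_threshold = th)))
  }, 0)
  expect_true(all(diff(counts) <= 0))
  # integer shift of the whole frame shifts decoded coordinates exactly
  pigs <- tibble::as_tibble(fr)
  shifted <- pigs
  for (nm in grep("_x$", names(pigs), value = TRUE)) shifted[[nm]] <- pigs[[nm]] + 7
  for (nm in grep("_y$", names(pigs), value = TRUE)) shifted[[nm]] <- pigs[[nm]] + 5
  fr2 <- frame_annotation(shifted, image_size = c(240 + 32, 320 + 32))
  fr1 <- frame_annotation(pigs, image_size = c(240 + 32, 320 + 32))
  d1 <- decode_maps(encode_frame(fr1))
  d2 <- decode_maps(encode_frame(fr2))
  expect_equal(nrow(d1), nrow(d2))
  o1 <- dplyr::arrange(tibble::as_tibble(d1), shoulder_x)
  o2 <- dplyr::arrange(tibble::as_tibble(d2), shoulder_x)
  expect_equal(o2$shoulder_x, o1$shoulder_x + 7, tolerance = 1e-9)
  expect_equal(o2$tail_y, o1$tail_y + 5, tolerance = 1e-9)
})

test_that("the optional assignment gate drops distant pairs and logs stages", {
  fr <- generate_fixture_suite(1)$chain$frame
  enc <- encode_frame(fr)
  # ungated euclidean on a chain pairs everything
  base <- decode_maps(enc, decoder_config(association_mode = "euclidean"))
  expect_equal(nrow(base), 3)
  # a tight gate removes every (long) shoulder-tail join
  gated <- decode_maps(enc, decoder_config(association_mode = "euclidean",
                                           max_assignment_distance = 10))
  expect_equal(nrow(gated), 0)
  # in vector mode ground-truth distances are ~0, so the gate keeps all
  gated_v <- decode_maps(enc, decoder_config(max_assignment_distance = 10))
  expect_equal(nrow(gated_v), 3)
  expect_message(decode_maps(enc, verbose = TRUE), "parts detected")
})

test_that("vector grouping is perfect on ground-truth encodings of the fixtures", {
  fx <- generate_fixture_suite(1)
  for (nm in setdiff(names(fx), "empty")) {
    fr <- fx[[nm]]$frame
    rep <- cross_check_match(fr, decode_maps(encode_frame(fr)))
    expect_equal(rep$recall, 1)
    expect_equal(rep$precision, 1)
  }
})
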