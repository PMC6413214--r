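test_that("kernel widths follow the size-adaptive rule", {
  fr <- one_pig_frame() # body length 100, mu = 100
  expect_equal(compute_sigma(fr), 32)
  fr2 <- frame_annotation(
    dplyr::bind_rows(make_pig(50, 40, 100, 40, id = 1L),
                     make_pig(50, 120, 200, 120, id = 2L)),
    image_size = c(240, 320)
  ) # lengths 50, 150, mu = 100
  expect_equal(compute_sigma(fr2), c(24, 40))
  fr3 <- frame_annotation(make_pig(5, 5, 5, 5), image_size = c(20, 20))
  expect_error(compute_sigma(fr3), "degenerate")
  expect_error(compute_sigma(frame_annotation(NULL, c(20, 20))), "empty")
})

test_that("part kernels are unit-peak Gaussians combined by maximum", {
  fr <- one_pig_frame()
  maps <- render_part_maps(fr)
  sh <- part_channel("shoulder")
  expect_equal(map_value(maps[, , sh], 50, 40), 1.0, tolerance = 1e-12)
  expect_equal(map_value(maps[, , sh], 50 + 32, 40), exp(-0.5), tolerance = 1e-9)
  expect_lte(max(maps), 1.0)
  # missing ears contribute nothing
  expect_equal(max(maps[, , part_channel("left_ear")]), 0)
  # overlapping same-channel kernels: pointwise maximum of the two kernels
  fa <- frame_annotation(make_pig(20, 30, 100, 100), image_size = c(160, 160))
  fb <- frame_annotation(make_pig(140, 30, 101, 100), image_size = c(160, 160))
  both <- frame_annotation(
    dplyr::bind_rows(make_pig(20, 30, 100, 100, id = 1L),
                     make_pig(140, 30, 101, 100, id = 2L)),
    image_size = c(160, 160)
  )
  s <- c(10, 10)
  combined <- render_part_maps(both, sigma = s)[, , part_channel("tail")]
  ka <- render_part_maps(fa, sigma = 10)[, , part_channel("tail")]
  kb <- render_part_maps(fb, sigma = 10)[, , part_channel("tail")]
  expect_equal(combined, pmax(ka, kb), tolerance = 1e-12)
})

test_that("association channels store source-minus-target offsets in 0.2-level discs", {
  fr <- frame_annotation(make_pig(50, 50, 80, 50), image_size = c(120, 160))
  sig <- compute_sigma(fr) # 0.16 * 60 = 9.6
  am <- render_assoc_maps(fr, sig)
  pair <- assoc_channels()
  st <- pair[pair$from == "shoulder" & pair$to == "tail", ]
  expect_equal(map_value(am$assoc[, , st$x_channel], 50, 50), -30)
  expect_equal(map_value(am$assoc[, , st$y_channel], 50, 50), 0)
  # mask is 1 exactly where the source kernel exceeds 0.2
  xs <- matrix(rep(0:159, each = 120), 120, 160)
  ys <- matrix(rep(0:119, times = 160), 120, 160)
  kern <- exp(-((xs - 50)^2 + (ys - 50)^2) / (2 * sig^2))
  expect_equal(am$mask[, , st$x_channel], (kern > 0.2) + 0)
})

test_that("intersecting equal-weight discs average the contributing vectors", {
  # two pigs with shoulders 16 px apart, equal sigma; the pixel equidistant
  # from both shoulders gets the unweighted mean of the two offsets
  both <- frame_annotation(
    dplyr::bind_rows(make_pig(42, 50, 42, 90, id = 1L),
                     make_pig(58, 50, 58, 10, id = 2L)),
    image_size = c(120, 160)
  )
  sig <- c(8, 8)
  am <- render_assoc_maps(both, sig)
  st <- assoc_channels()
  st <- st[st$from == "shoulder" & st$to == "tail", ]
  # offsets: pig1 (0, -40), pig2 (0, 40); midpoint (50, 50)
  expect_equal(map_value(am$assoc[, , st$y_channel], 50, 50), 0, tolerance = 1e-9)
  expect_equal(map_value(am$assoc[, , st$x_channel], 50, 50), 0, tolerance = 1e-9)
  # off-centre pixel: kernel-magnitude weighted average
  w1 <- exp(-((44 - 42)^2) / (2 * 64)); w2 <- exp(-((44 - 58)^2) / (2 * 64))
  expected <- (w1 * (-40) + w2 * 40) / (w1 + w2)
  expect_equal(map_value(am$assoc[, , st$y_channel], 44, 50), expected, tolerance = 1e-9)
})

test_that("maps are zero wherever the mask is zero and empty frames encode to zero", {
  enc0 <- encode_frame(frame_annotation(NULL, c(80, 100)))
  expect_equal(max(abs(enc0$part)), 0)
  expect_equal(max(abs(enc0$assoc)), 0)
  expect_equal(max(enc0$mask), 0)
  set.seed(11)
  for (s in 1:3) {
    fr <- random_separated_frame(s, n_range = c(2, 4), size = c(240, 320),
                                 len_range = c(30, 60))
    enc <- encode_frame(fr)
    expect_equal(max(abs(enc$assoc * (1 - enc$mask))), 0)
    expect_lte(max(enc$part), 1 + 1e-12)
  }
})

test_that("composed tail->shoulder->left-ear vectors reproduce the direct ear position", {
  fr <- frame_annotation(
    make_pig(100, 80, 160, 80, lx = 80, ly = 60, rx = 80, ry = 100),
    image_size = c(200, 260)
  )
  enc <- encode_frame(fr)
  s_hat <- sample_association(enc$assoc, c(160, 80), "tail", "shoulder")
  expect_equal(s_hat, c(100, 80), tolerance = 1e-9)
  l_hat <- sample_association(enc$assoc, s_hat, "shoulder", "left_ear")
  expect_equal(l_hat, c(80, 60), tolerance = 1e-6)
})

test_that("encoding then decoding recovers every instance to sub-half-pixel", {
  set.seed(23)
  for (s in c(101, 202, 303)) {
    fr <- random_separated_frame(s)
    det <- decode_maps(encode_frame(fr))
    rep <- cross_check_match(fr, det)
    expect_equal(rep$tp, nrow(fr))
    expect_equal(rep$fp, 0)
    for (k in seq_len(nrow(rep$matched_pairs))) {
      g <- rep$matched_pairs$gt_index[k]; d <- rep$matched_pairs$det_index[k]
      expect_lt(euclidean_norm(
        c(fr$shoulder_x[g], fr$shoulder_y[g]),
        c(det$shoulder_x[d], det$shoulder_y[d])
      ), 0.5)
      expect_lt(euclidean_norm(
        c(fr$tail_x[g], fr$tail_y[g]),
        c(det$tail_x[d], det$tail_y[d])
      ), 0.5)
    }
  }
})
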