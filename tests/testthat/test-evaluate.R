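test_that("instance cost sums shoulder and tail distances and excludes ears", {
  a <- make_pig(0, 0, 10, 0, lx = 5, ly = 5)
  b <- make_pig(0, 0, 10, 0, lx = 90, ly = 90)
  expect_equal(instance_cost(a, b), 0) # ear positions do not matter
  c1 <- make_pig(0, 0, 0, 10)
  c2 <- make_pig(3, 0, 4, 10)
  expect_equal(instance_cost(c1, c2), 7)
  expect_equal(instance_cost(c2, c1), instance_cost(c1, c2))
})

test_that("cross-check matching keeps only mutual minimum-cost pairs", {
  # cost matrix [[2,9],[1,5]]: gt b and det x are mutual minima; the
  # Hungarian assignment on the same matrix pairs everything
  D <- rbind(c(2, 9), c(1, 5))
  rep <- pigparts:::match_report_from_cost(D)
  expect_equal(rep$tp, 1)
  expect_equal(rep$fp, 1)
  expect_equal(rep$fn, 1)
  expect_equal(rep$matched_pairs$gt_index, 2L)
  expect_equal(rep$matched_pairs$det_index, 1L)
  expect_equal(nrow(hungarian_assign(D)), 2)
})

test_that("empty-set conventions and perfect matches behave as defined", {
  gt <- dplyr::bind_rows(make_pig(10, 10, 60, 10, id = 1L),
                         make_pig(10, 80, 60, 80, id = 2L))
  none <- gt[0, ]
  r1 <- cross_check_match(gt, none)
  expect_equal(c(r1$tp, r1$fp, r1$fn), c(0, 0, 2))
  expect_equal(r1$precision, 1) # no detections -> no false alarms
  expect_equal(r1$recall, 0)
  r2 <- cross_check_match(gt, gt)
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(2, 0, 0))
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, 1)
  m <- compute_metrics(0, 0, 0)
  expect_equal(unlist(m), c(precision = 1, recall = 1, f_measure = 1))
})

test_that("metric arithmetic reproduces the published threshold-sweep tables", {
  # corpus-level TP/FP/FN counts with their printed (recall, precision, F)
  vec <- rbind(
    c(0.10, 20217, 27, 525, 0.975, 0.999, 0.987),
    c(0.15, 20160, 20, 582, 0.972, 0.999, 0.985),
    c(0.20, 20092, 17, 650, 0.969, 0.999, 0.984),
    c(0.25, 19999, 13, 743, 0.964, 0.999, 0.981),
    c(0.30, 19865, 10, 877, 0.958, 0.999, 0.978),
    c(0.35, 19675, 7, 1067, 0.949, 1.000, 0.973),
    c(0.40, 19413, 3, 1329, 0.936, 1.000, 0.967),
    c(0.45, 19029, 2, 1713, 0.917, 1.000, 0.957),
    c(0.50, 18408, 2, 2334, 0.887, 1.000, 0.940),
    c(0.55, 17287, 2, 3455, 0.833, 1.000, 0.909),
    c(0.60, 15227, 2, 5515, 0.734, 1.000, 0.847),
    c(0.65, 11929, 0, 8813, 0.575, 1.000, 0.730),
    c(0.70, 7565, 0, 13177, 0.365, 1.000, 0.534),
    c(0.75, 3261, 0, 17481, 0.157, 1.000, 0.272),
    c(0.80, 692, 0, 20050, 0.033, 1.000, 0.065),
    c(0.85, 53, 0, 20689, 0.003, 1.000, 0.005),
    c(0.90, 1, 0, 20741, 0.000, 1.000, 0.000)
  )
  euc <- rbind(
    c(19170, 1181, 1572, 0.924, 0.942, 0.933),
    c(18971, 1141, 1771, 0.915, 0.943, 0.929),
    c(5, 0, 20737, 0.000, 1.000, 0.000)
  )
  sets <- rbind(
    c(19999, 13, 743, 0.964, 0.999, 0.981),   # training
    c(2273, 1, 94, 0.960, 1.000, 0.980),      # seen environments
    c(1150, 112, 573, 0.667, 0.911, 0.771)    # unseen environments
  )
  check_rows <- function(tab, off = 0) {
    for (i in seq_len(nrow(tab))) {
      m <- compute_metrics(tab[i, off + 1], tab[i, off + 2], tab[i, off + 3])
      expect_equal(round(m$recall, 3), tab[i, off + 4])
      expect_equal(round(m$precision, 3), tab[i, off + 5])
      expect_equal(round(m$f_measure, 3), tab[i, off + 6])
    }
  }
  check_rows(vec, off = 1)
  check_rows(euc)
  check_rows(sets)
})

test_that("cross-check is symmetric and never exceeds the Hungarian match count", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    gt <- tibble::tibble(
      shoulder_x = stats::runif(n, 0, 200), shoulder_y = stats::runif(n, 0, 200),
      tail_x = stats::runif(n, 0, 200), tail_y = stats::runif(n, 0, 200)
    )
    det <- tibble::tibble(
      shoulder_x = stats::runif(m, 0, 200), shoulder_y = stats::runif(m, 0, 200),
      tail_x = stats::runif(m, 0, 200), tail_y = stats::runif(m, 0, 200)
    )
    fwd <- cross_check_match(gt, det)
    bwd <- cross_check_match(det, gt)
    expect_equal(fwd$tp, bwd$tp)
    expect_equal(fwd$fp, bwd$fn)
    expect_equal(fwd$fn, bwd$fp)
    D <- pigparts:::instance_cost_matrix(gt, det)
    expect_lte(fwd$tp, nrow(hungarian_assign(D)))
  }
})

test_that("tidiers expose counts and matches", {
  gt <- dplyr::bind_rows(make_pig(10, 10, 60, 10, id = 1L),
                         make_pig(10, 80, 60, 80, id = 2L))
  rep <- cross_check_match(gt, gt)
  g <- glance(rep)
  expect_equal(g$tp, 2)
  expect_equal(g$f_measure, 1)
  expect_equal(nrow(tidy(rep)), 2)
})

test_that("threshold sweeps aggregate micro-averaged counts", {
  fx <- generate_fixture_suite(1)
  frames <- purrr::map(fx[c("single", "chain")], function(s) {
    list(frame = s$frame, maps = encode_frame(s$frame))
  })
  curve <- pr_sweep(frames, thresholds = c(0.15, 0.5, 0.8))
  expect_s3_class(curve, "pr_curve")
  expect_equal(curve$precision, rep(1, 3))
  expect_equal(curve$recall, rep(1, 3))
  expect_equal(curve$tp[1], 4) # 1 + 3 instances
  # maps with peak 0.9: a 0.99 threshold detects nothing
  scaled <- frames
  for (i in seq_along(scaled)) {
    scaled[[i]]$maps$part <- scaled[[i]]$maps$part * 0.9
  }
  hi <- pr_sweep(scaled, thresholds = c(0.5, 0.99))
  expect_equal(hi$recall[2], 0)
  expect_equal(hi$fp[2], 0)
  # recall is non-increasing along the threshold grid
  expect_true(all(diff(hi$recall) <= 0))
  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
})
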