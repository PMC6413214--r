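test_that("effective strides and receptive field reproduce the architecture profile", {
  spec <- hourglass_spec()
  expect_equal(nrow(spec), 41)
  s <- effective_strides(spec)
  r <- receptive_field(spec)
  # head of the profile: input, two convs, pool, conv
  expect_equal(r[1:5], c(1, 3, 5, 5, 9))
  expect_equal(s[1:5], c(1, 1, 1, 2, 2))
  # bottleneck: last encoder conv at stride 16 sees 181; the 5th pool
  # doubles the stride to its maximum of 32
  expect_equal(r[18], 181)
  expect_equal(s[18], 16)
  expect_equal(s[19], 32)
  expect_equal(max(s), 32)
  # output: stride returns to 1, receptive field 363, radius 181
  expect_equal(s[41], 1)
  expect_equal(utils::tail(r, 3), c(359, 361, 363))
  expect_equal((r[41] - 1) / 2, 181)
  # a conv-free prefix has stride 1 throughout; stacked 3x3 convs grow r by 2
  expect_equal(r[2] - r[1], 2)
  expect_equal(r[3] - r[2], 2)
})

test_that("unpooling stages pair with pooling stages at matching channels", {
  spec <- hourglass_spec(c(8L, 16L, 24L, 32L, 32L))
  pools <- spec[spec$kind == "pool", ]
  unpools <- spec[spec$kind == "unpool", ]
  expect_equal(nrow(pools), 5)
  expect_equal(nrow(unpools), 5)
  for (pid in 1:5) {
    expect_equal(unpools$channels_in[unpools$pool_id == pid],
                 pools$channels_out[pools$pool_id == pid])
  }
  concats <- spec[spec$kind == "concat", ]
  expect_equal(nrow(concats), 5)
  # each concat pulls from a conv block with the same resolution
  expect_equal(spec$kind[concats$skip_block], rep("conv", 5))
})

test_that("the default width profile lands near four million coefficients", {
  n <- count_parameters(hourglass_spec())
  expect_gte(n, 3.5e6)
  expect_lte(n, 4.5e6)
})

test_that("the model maps any 32-divisible image to a 16-channel map of equal size", {
  model <- build_model(hourglass_spec(c(2L, 3L, 3L, 4L, 4L)), seed = 2)
  img <- array(stats::runif(64 * 96 * 3), c(64, 96, 3))
  out <- predict_maps(model, img)
  expect_equal(dim(out), c(64, 96, 16))
  # repeated forward passes are deterministic
  expect_identical(out, predict_maps(model, img))
  # non-divisible sizes are padded then cropped
  img2 <- array(stats::runif(50 * 70 * 3), c(50, 70, 3))
  expect_equal(dim(predict_maps(model, img2)), c(50, 70, 16))
})

test_that("selective loss masks association gradients exactly", {
  fr <- frame_annotation(make_pig(20, 30, 45, 34), image_size = c(64, 64))
  tgt <- encode_frame(fr)
  pred <- target_stack(tgt)
  expect_equal(selective_loss(pred, tgt), 0)
  # perturbing an association channel where the mask is zero changes nothing
  pred2 <- pred
  off_mask <- tgt$mask[, , 5] == 0
  ch <- pred2[, , 9]
  ch[off_mask] <- ch[off_mask] + 100
  pred2[, , 9] <- ch
  expect_equal(selective_loss(pred2, tgt), 0)
  sl <- selective_loss(pred2, tgt, with_grad = TRUE)
  expect_equal(max(abs(sl$grad)), 0)
  # constant offset on part channels: part term is c^2
  pred3 <- pred
  pred3[, , 1:4] <- pred3[, , 1:4] + 0.3
  expect_equal(selective_loss(pred3, tgt), 0.09, tolerance = 1e-12)
  expect_error(selective_loss(pred[1:32, , , drop = FALSE], tgt), "shape|match")
})

test_that("backpropagated gradients agree with finite differences", {
  spec <- hourglass_spec(c(2L, 3L, 3L, 4L, 4L))
  model <- build_model(spec, seed = 3)
  set.seed(5)
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  fr <- frame_annotation(make_pig(20, 30, 45, 34), image_size = c(64, 64))
  tgt <- encode_frame(fr)
  fwd <- pigparts:::net_forward(model, img, keep_cache = TRUE)
  sl <- selective_loss(fwd$out, tgt, with_grad = TRUE)
  grads <- pigparts:::net_backward(model, fwd, sl$grad)
  eps <- 1e-5
  for (probe in list(c(9, 10), c(22, 4), c(41, 3))) {
    l <- probe[1]; idx <- probe[2]
    m2 <- model
    m2$params[[l]]$w[idx] <- m2$params[[l]]$w[idx] + eps
    lp <- selective_loss(pigparts:::net_forward(m2, img)$out, tgt)
    m2$params[[l]]$w[idx] <- m2$params[[l]]$w[idx] - 2 * eps
    lm <- selective_loss(pigparts:::net_forward(m2, img)$out, tgt)
    num <- (lp - lm) / (2 * eps)
    expect_equal(grads[[l]]$w[idx], num, tolerance = 1e-4)
  }
})

test_that("training overfits a single frame and reproduces under a fixed seed", {
  sc <- generate_scene(scene_config(image_size = c(64L, 64L), n_pigs = c(1L, 1L),
                                    length_range = c(18, 26),
                                    abutting_fraction = 0), seed = 3)
  model <- build_model(hourglass_spec(c(4L, 6L, 8L, 8L, 8L)), seed = 1)
  cfg <- train_config(epochs = 50, batch_size = 1, lr = 8e-3, seed = 7)
  fit <- train_model(model, list(sc), cfg)
  expect_lt(utils::tail(fit$history$loss, 1), 0.1 * fit$history$loss[1])
  # identical seeds give identical loss histories
  short <- train_config(epochs = 2, batch_size = 1, lr = 3e-3, seed = 7)
  h1 <- train_model(build_model(hourglass_spec(c(4L, 6L, 8L, 8L, 8L)), seed = 1),
                    list(sc), short)$history
  h2 <- train_model(build_model(hourglass_spec(c(4L, 6L, 8L, 8L, 8L)), seed = 1),
                    list(sc), short)$history
  expect_identical(h1, h2)
})
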