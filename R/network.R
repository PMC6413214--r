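#' The 41-block hourglass architecture specification
#'
#' An encoder-decoder ("hourglass") fully-convolutional network mapping an
#' RGB image to the 16-channel part/association representation at input
#' resolution. The encoder applies 3x3 convolution blocks (convolution +
#' per-channel normalisation + ReLU) interleaved with five 2x2 max-pooling
#' stages; the decoder mirrors it with five max-unpooling stages that reuse
#' the pooling indices of their paired pooling blocks, each immediately
#' followed by a depth concatenation with the encoder feature map of the
#' same resolution (a skip connection), and a final 3x3 convolution to 16
#' output channels. Convolutions have stride 1 and width 3; pooling blocks
#' have stride 2, unpooling 0.5, and both use the kernel-width lower bound
#' of 1 in the receptive-field analysis.
#'
#' @param widths integer vector of 5 channel widths, one per resolution
#'   level (level 1 = full resolution). The default lands the parameter
#'   count near 4 million.
#' @return A tibble with one row per layer block: `l`, `kind` (one of
#'   `input`, `conv`, `pool`, `unpool`, `concat`, `output`), `stride`,
#'   `kernel_width`, `channels_in`, `channels_out`, `pool_id` (pairing
#'   pools with unpools) and `skip_block` (encoder source of each concat).
#' @export
#' @examples
#' spec <- hourglass_spec()
#' nrow(spec) # 41
#' max(effective_strides(spec)) # 32
#' tail(receptive_field(spec), 1) # 363
hourglass_spec <- function(widths = c(40L, 80L, 120L, 160L, 160L)) {
  stopifnot(length(widths) == 5, all(widths >= 1))
  w <- as.integer(widths)
  enc_convs <- c(2L, 2L, 3L, 3L, 3L)
  dec_convs <- c(4L, 2L, 1L, 2L) # at levels 5,4,3,2 after each unpool
  rows <- list()
  add <- function(kind, stride, kw, cin, cout, pool_id = NA_integer_,
                  skip_block = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, stride = stride, kernel_width = kw,
      channels_in = cin, channels_out = cout,
      pool_id = pool_id, skip_block = skip_block
    )
  }
  add("input", 1, 1L, 3L, 3L)
  ch <- 3L
  skip_blocks <- integer(5) # last conv block index at each level
  for (lev in 1:5) {
    for (k in seq_len(enc_convs[lev])) {
      add("conv", 1, 3L, ch, w[lev])
      ch <- w[lev]
    }
    skip_blocks[lev] <- length(rows)
    add("pool", 2, 1L, ch, ch, pool_id = lev)
  }
  for (lev in 5:1) {
    add("unpool", 0.5, 1L, ch, ch, pool_id = lev)
    skip_ch <- w[lev]
    add("concat", 1, 1L, ch, ch + skip_ch, skip_block = skip_blocks[lev])
    ch <- ch + skip_ch
    n_conv <- if (lev >= 2) dec_convs[6 - lev] else 2L
    # the last conv of each level steps down to the next level's width so
    # the following unpool matches its paired pool's channel count
    for (k in seq_len(n_conv)) {
      cout <- if (k == n_conv && lev >= 2) w[lev - 1] else w[lev]
      add("conv", 1, 3L, ch, cout)
      ch <- cout
    }
  }
  add("output", 1, 3L, ch, 16L)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, l = dplyr::row_number(), .before = 1)
  stopifnot(nrow(out) == 41)
  tibble::new_tibble(out, class = "network_spec")
}

#' Effective stride per layer block
#'
#' The cumulative product of block strides: `s_eff(l) = s_eff(l-1) * s(l)`
#' with `s_eff(0) = 1`. It relates each feature map's resolution to the
#' input resolution; in the hourglass it rises to 32 at the bottleneck and
#' returns to 1 at the output.
#'
#' @param spec a [hourglass_spec()] tibble.
#' @return Numeric vector, one value per block.
#' @export
effective_strides <- function(spec) {
  cumprod(spec$stride)
}

#' Receptive field per layer block
#'
#' The recursion `r(l) = r(l-1) + (w(l) - 1) * s_eff(l-1)` with `r(0) = 1`,
#' where `w(l)` is the kernel width (3 for convolutions, lower-bounded at 1
#' for pooling/unpooling/concatenation). The final value is the width of
#' the square input region that can influence one output pixel; half of
#' `r - 1` is the radius within which two image locations can affect each
#' other's outputs.
#'
#' @param spec a [hourglass_spec()] tibble.
#' @return Numeric vector, one value per block.
#' @export
receptive_field <- function(spec) {
  s_eff <- effective_strides(spec)
  r <- numeric(nrow(spec))
  prev_r <- 1
  prev_s <- 1
  for (l in seq_len(nrow(spec))) {
    r[l] <- prev_r + (spec$kernel_width[l] - 1) * prev_s
    prev_r <- r[l]
    prev_s <- s_eff[l]
  }
  r
}

#' Count trainable parameters of a network spec
#'
#' Convolution blocks contribute `9 * Cin * Cout` kernel weights, `Cout`
#' biases and `2 * Cout` normalisation parameters; the output convolution
#' has kernel and bias only.
#'
#' @param spec a [hourglass_spec()] tibble.
#' @return Total number of scalar parameters.
#' @export
count_parameters <- function(spec) {
  n <- 0
  for (l in seq_len(nrow(spec))) {
    k <- spec$kind[l]
    if (k == "conv") {
      n <- n + 9 * spec$channels_in[l] * spec$channels_out[l] + 3 * spec$channels_out[l]
    } else if (k == "output") {
      n <- n + 9 * spec$channels_in[l] * spec$channels_out[l] + spec$channels_out[l]
    }
  }
  n
}

#' Build a trainable hourglass model
#'
#' Allocates He-initialised convolution weights for every block of the
#' spec. The model maps `[R, C, 3]` images to `[R, C, 16]` maps for any
#' spatial size; inputs not divisible by 32 are replicate-padded and the
#' output cropped back.
#'
#' @param spec a [hourglass_spec()]; use small widths for desk-scale
#'   training.
#' @param seed integer seed for weight initialisation.
#' @return An `hourglass_model` object.
#' @export
build_model <- function(spec = hourglass_spec(), seed = 1L) {
  params <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(nrow(spec)), function(l) {
      k <- spec$kind[l]
      if (k %in% c("conv", "output")) {
        cin <- spec$channels_in[l]; cout <- spec$channels_out[l]
        p <- list(
          w = matrix(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                     9 * cin, cout),
          b = numeric(cout)
        )
        if (k == "conv") {
          p$gamma <- rep(1, cout)
          p$beta <- numeric(cout)
        }
        p
      } else {
        NULL
      }
    })
  })
  structure(list(spec = spec, params = params, opt = NULL),
            class = "hourglass_model")
}

#' @export
print.hourglass_model <- function(x, ...) {
  cat(sprintf("<hourglass_model> 41 blocks, %s parameters\n",
              format(count_parameters(x$spec), big.mark = ",")))
  invisible(x)
}

# per-channel spatial normalisation (suits batches of one image)
norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3])
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  v <- colMeans(ctr^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(ctr, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, dim = d)
}

norm_backward <- function(cache, gamma, gy) {
  d <- cache$dim
  g <- gy
  dim(g) <- c(d[1] * d[2], d[3])
  n <- d[1] * d[2]
  gbeta <- colSums(g)
  ggamma <- colSums(g * cache$xhat)
  gxhat <- sweep(g, 2, gamma, `*`)
  t1 <- sweep(gxhat, 2, colSums(gxhat) / n)
  t2 <- sweep(cache$xhat, 2, colSums(gxhat * cache$xhat) / n, `*`)
  gx <- sweep(t1 - t2, 2, cache$istd, `*`)
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# forward pass; returns output and (optionally) per-block caches
net_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  nb <- nrow(spec)
  outs <- vector("list", nb)
  caches <- if (keep_cache) vector("list", nb) else NULL
  pool_idx <- vector("list", 5)
  pool_insize <- vector("list", 5)
  a <- x
  for (l in seq_len(nb)) {
    k <- spec$kind[l]
    if (k == "input") {
      # identity
    } else if (k == "conv") {
      p <- model$params[[l]]
      pre <- conv3x3_forward(a, p$w, p$b)
      nf <- norm_forward(pre, p$gamma, p$beta)
      a2 <- pmax(nf$y, 0)
      if (keep_cache) {
        caches[[l]] <- list(x = a, norm = nf, relu_mask = nf$y > 0)
      }
      a <- a2
    } else if (k == "output") {
      p <- model$params[[l]]
      out <- conv3x3_forward(a, p$w, p$b)
      if (keep_cache) caches[[l]] <- list(x = a)
      a <- out
    } else if (k == "pool") {
      pid <- spec$pool_id[l]
      pool_insize[[pid]] <- dim(a)[1:2]
      res <- maxpool2(a)
      pool_idx[[pid]] <- res$idx
      a <- res$y
    } else if (k == "unpool") {
      pid <- spec$pool_id[l]
      sz <- pool_insize[[pid]]
      a <- maxunpool2(a, pool_idx[[pid]], sz[1], sz[2])
    } else if (k == "concat") {
      skip <- outs[[spec$skip_block[l]]]
      d1 <- dim(a); d2 <- dim(skip)
      merged <- array(0, c(d1[1], d1[2], d1[3] + d2[3]))
      merged[, , seq_len(d1[3])] <- a
      merged[, , d1[3] + seq_len(d2[3])] <- skip
      if (keep_cache) caches[[l]] <- list(split = d1[3])
      a <- merged
    }
    outs[[l]] <- a
  }
  list(out = a, outs = outs, caches = caches,
       pool_idx = pool_idx, pool_insize = pool_insize)
}

# backward pass; returns list of per-block parameter gradients
net_backward <- function(model, fwd, gout) {
  spec <- model$spec
  nb <- nrow(spec)
  grads <- vector("list", nb)
  # gradients flowing into each block's *output*; skips add extra terms
  gacc <- vector("list", nb)
  gacc[[nb]] <- gout
  g <- NULL
  for (l in nb:1) {
    k <- spec$kind[l]
    g <- gacc[[l]]
    if (is.null(g)) next
    prev <- l - 1L
    if (k == "conv") {
      cache <- fwd$caches[[l]]
      p <- model$params[[l]]
      g <- g * cache$relu_mask
      nb_ <- norm_backward(cache$norm, p$gamma, g)
      cb <- conv3x3_backward(cache$x, p$w, nb_$gx)
      grads[[l]] <- list(w = cb$gw, b = cb$gb, gamma = nb_$ggamma, beta = nb_$gbeta)
      g <- cb$gx
    } else if (k == "output") {
      cache <- fwd$caches[[l]]
      p <- model$params[[l]]
      cb <- conv3x3_backward(cache$x, p$w, g)
      grads[[l]] <- list(w = cb$gw, b = cb$gb)
      g <- cb$gx
    } else if (k == "pool") {
      pid <- spec$pool_id[l]
      sz <- fwd$pool_insize[[pid]]
      g <- maxpool2_backward(fwd$pool_idx[[pid]], g, sz[1], sz[2])
    } else if (k == "unpool") {
      pid <- spec$pool_id[l]
      g <- maxunpool2_backward(g, fwd$pool_idx[[pid]])
    } else if (k == "concat") {
      split <- fwd$caches[[l]]$split
      gskip <- g[, , (split + 1):dim(g)[3], drop = FALSE]
      sb <- spec$skip_block[l]
      gacc[[sb]] <- if (is.null(gacc[[sb]])) gskip else gacc[[sb]] + gskip
      g <- g[, , seq_len(split), drop = FALSE]
    } else if (k == "input") {
      next
    }
    if (prev >= 1) {
      gacc[[prev]] <- if (is.null(gacc[[prev]])) g else gacc[[prev]] + g
    }
  }
  grads
}

pad_to_multiple <- function(image, m = 32L) {
  d <- dim(image)
  r2 <- as.integer(ceiling(d[1] / m) * m)
  c2 <- as.integer(ceiling(d[2] / m) * m)
  if (r2 == d[1] && c2 == d[2]) return(list(image = image, crop = d[1:2]))
  ridx <- c(seq_len(d[1]), rep(d[1], r2 - d[1]))
  cidx <- c(seq_len(d[2]), rep(d[2], c2 - d[2]))
  list(image = image[ridx, cidx, , drop = FALSE], crop = d[1:2])
}

#' Run the network on an image
#'
#' Pads the input to a multiple of 32 (replicate padding), runs the forward
#' pass and crops the 16-channel output back to the input size.
#'
#' @param model an [build_model()] result.
#' @param image `[R, C, 3]` array in `[0, 1]`.
#' @return `[R, C, 16]` array.
#' @export
predict_maps <- function(model, image) {
  pd <- pad_to_multiple(image)
  out <- net_forward(model, pd$image, keep_cache = FALSE)$out
  out[seq_len(pd$crop[1]), seq_len(pd$crop[2]), , drop = FALSE]
}

#' Selective masked training loss
#'
#' Mean-squared error with the selective association masking: the four part
#' channels contribute everywhere, the twelve association channels only at
#' pixels where the assignment mask is set (each term normalised by its own
#' pixel count). Gradients with respect to association outputs are exactly
#' zero at masked-out pixels, so the network is free to guess vectors where
#' no part is present.
#'
#' Association offsets are measured in pixels, so at initialisation the
#' association term is orders of magnitude larger than the part term and
#' can monopolise a short optimisation run. `assoc_weight` scales the
#' association term (1 keeps the canonical loss; the desk-scale training
#' demonstrations use a small value so both heads train within the budget
#' -- grouping a handful of well-separated animals tolerates offset errors
#' of several pixels).
#'
#' @param pred `[R, C, 16]` network output.
#' @param target a `target_maps` object of the same spatial size.
#' @param with_grad also return the gradient array.
#' @param assoc_weight multiplier on the association term.
#' @return Scalar loss, or (with `with_grad`) a list `loss`, `grad`.
#' @export
selective_loss <- function(pred, target, with_grad = FALSE, assoc_weight = 1) {
  stopifnot(inherits(target, "target_maps"))
  d <- dim(pred)
  if (!all(d == c(target$image_size, 16L))) {
    stop("prediction shape ", paste(d, collapse = "x"),
         " does not match target ", paste(target$image_size, collapse = "x"))
  }
  part_diff <- pred[, , 1:4, drop = FALSE] - target$part
  n_part <- length(part_diff)
  part_term <- sum(part_diff^2) / n_part
  assoc_diff <- (pred[, , 5:16, drop = FALSE] - target$assoc) * target$mask
  n_mask <- sum(target$mask)
  assoc_term <- if (n_mask > 0) sum(assoc_diff^2) / n_mask else 0
  loss <- part_term + assoc_weight * assoc_term
  if (!with_grad) return(loss)
  grad <- array(0, d)
  grad[, , 1:4] <- 2 * part_diff / n_part
  if (n_mask > 0) grad[, , 5:16] <- 2 * assoc_weight * assoc_diff / n_mask
  list(loss = loss, grad = grad)
}

#' Training configuration
#'
#' @param epochs passes over the training scenes.
#' @param lr,beta1,beta2,eps Adam hyper-parameters.
#' @param batch_size images per parameter update.
#' @param augment an [augment_spec()] applied per step (annotation-space
#'   augmentation followed by re-encoding), or `NULL` for none.
#' @param assoc_weight association-term weight passed to [selective_loss()].
#' @param seed seed controlling shuffling, augmentation draws and
#'   initial state reproducibility.
#' @param verbose print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 8L, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, batch_size = 4L, augment = NULL,
                         assoc_weight = 1, seed = 1L, verbose = FALSE) {
  structure(
    list(epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
         eps = eps, batch_size = as.integer(batch_size), augment = augment,
         assoc_weight = assoc_weight, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

#' Train the hourglass network on annotated scenes
#'
#' Minimises the [selective_loss()] with Adam. Each step optionally draws a
#' fresh spatial augmentation, applies it to the annotation, re-encodes the
#' target maps, and back-propagates. Training aborts with a diagnostic if
#' the loss turns non-finite. With a fixed config seed the loss history is
#' bit-reproducible.
#'
#' @param model an [build_model()] result.
#' @param scenes list of scenes, each a list with `image` and `frame` (as
#'   produced by [generate_scene()]).
#' @param config a [train_config()].
#' @return List with the trained `model` and `history`, a tibble of
#'   per-epoch mean losses.
#' @export
train_model <- function(model, scenes, config = train_config()) {
  stopifnot(length(scenes) >= 1)
  n <- length(scenes)
  # pre-encode targets once when not augmenting
  static_targets <- if (is.null(config$augment)) {
    purrr::map(scenes, function(s) encode_frame(s$frame))
  } else {
    NULL
  }
  state <- init_adam(model)
  history <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      batch_grads <- NULL
      batch_count <- 0L
      for (i in ord) {
        sc <- scenes[[i]]
        if (is.null(config$augment)) {
          img <- sc$image
          tgt <- static_targets[[i]]
        } else {
          draw <- draw_augment(config$augment)
          aug <- tryCatch(augment_frame(sc$frame, draw), error = function(e) NULL)
          if (is.null(aug) || nrow(aug) == 0) {
            img <- sc$image
            tgt <- encode_frame(sc$frame)
          } else {
            img <- augment_image(sc$image, draw)
            tgt <- encode_frame(aug)
          }
        }
        pd <- pad_to_multiple(img)
        fwd <- net_forward(model, pd$image, keep_cache = TRUE)
        pred <- fwd$out[seq_len(pd$crop[1]), seq_len(pd$crop[2]), , drop = FALSE]
        sl <- selective_loss(pred, tgt, with_grad = TRUE,
                             assoc_weight = config$assoc_weight)
        if (!is.finite(sl$loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (try a lower learning rate)")
        }
        losses <- c(losses, sl$loss)
        gout <- array(0, dim(fwd$out))
        gout[seq_len(pd$crop[1]), seq_len(pd$crop[2]), ] <- sl$grad
        grads <- net_backward(model, fwd, gout)
        batch_grads <- accumulate_grads(batch_grads, grads)
        batch_count <- batch_count + 1L
        if (batch_count == config$batch_size) {
          step <- step + 1L
          model <- adam_update(model, state, batch_grads, batch_count, config, step)
          batch_grads <- NULL
          batch_count <- 0L
        }
      }
      if (batch_count > 0) {
        step <- step + 1L
        model <- adam_update(model, state, batch_grads, batch_count, config, step)
      }
      history[epoch] <- mean(losses)
      if (config$verbose) {
        message(sprintf("epoch %d/%d  loss %.5f", epoch, config$epochs, history[epoch]))
      }
    }
  })
  list(model = model,
       history = tibble::tibble(epoch = seq_len(config$epochs), loss = history))
}

init_adam <- function(model) {
  e <- new.env()
  e$m <- purrr::map(model$params, function(p) {
    if (is.null(p)) NULL else purrr::map(p, function(v) v * 0)
  })
  e$v <- e$m
  e
}

accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (l in seq_along(grads)) {
    if (is.null(grads[[l]])) next
    for (nm in names(grads[[l]])) {
      acc[[l]][[nm]] <- acc[[l]][[nm]] + grads[[l]][[nm]]
    }
  }
  acc
}

adam_update <- function(model, state, grads, batch_count, config, step) {
  b1 <- config$beta1; b2 <- config$beta2
  corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
  for (l in seq_along(model$params)) {
    p <- model$params[[l]]
    if (is.null(p) || is.null(grads[[l]])) next
    for (nm in names(p)) {
      g <- grads[[l]][[nm]] / batch_count
      state$m[[l]][[nm]] <- b1 * state$m[[l]][[nm]] + (1 - b1) * g
      state$v[[l]][[nm]] <- b2 * state$v[[l]][[nm]] + (1 - b2) * g^2
      mhat <- state$m[[l]][[nm]] / corr1
      vhat <- state$v[[l]][[nm]] / corr2
      model$params[[l]][[nm]] <- p[[nm]] - config$lr * mhat / (sqrt(vhat) + config$eps)
      p[[nm]] <- model$params[[l]][[nm]]
    }
  }
  model
}
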